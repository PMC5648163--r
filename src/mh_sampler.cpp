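#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Metropolis-Hastings over monotone mineralization trajectories.
//
// State: a density trajectory on the pixel's (strictly increasing) time
// grid. Target: Gaussian likelihood sum_t -(m_t - d_t)^2 / (2 sigma_t^2)
// with a flat prior on the feasible set {0 <= m_1, m_{t+1} >= m_t +
// min_inc, m_T <= ceiling}. Proposals perturb one uniformly chosen time
// point (Gaussian step in continuous mode; symmetric level jump in grid
// mode); infeasible candidates are rejected outright, which leaves the
// flat-prior posterior invariant.

static inline double loglik_point(double m, double d, double sigma) {
  double r = m - d;
  return -r * r / (2.0 * sigma * sigma);
}

// [[Rcpp::export]]
List mh_sample_pixel_cpp(NumericVector rho, NumericVector sigma,
                         int n_samples, int n_walkers, int n_keep,
                         double min_inc, double ceiling,
                         double burn_in_frac, double target_acceptance,
                         double init_step, double seed,
                         NumericVector grid_levels) {
  const int T = rho.size();
  const bool grid_mode = grid_levels.size() > 0;
  const int L = grid_levels.size();
  const int per_chain = n_samples / n_walkers;
  const int burn = (int)std::floor(per_chain * burn_in_frac);
  const int post = per_chain - burn;

  // retained samples split as evenly as possible across walkers
  std::vector<int> keep_w(n_walkers, n_keep / n_walkers);
  for (int w = 0; w < n_keep % n_walkers; ++w) keep_w[w] += 1;

  NumericMatrix samples(n_keep, T);
  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 104729ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  long long n_acc = 0, n_prop = 0;
  int out_row = 0;

  // feasible monotone initialization: pool-adjacent-violators on the data,
  // then minimum-increment and ceiling enforcement
  std::vector<double> base(T);
  {
    // PAVA (unweighted)
    std::vector<double> level(T);
    std::vector<int> count(T);
    int k = 0;
    for (int t = 0; t < T; ++t) {
      level[k] = rho[t];
      count[k] = 1;
      while (k > 0 && level[k - 1] > level[k]) {
        double merged = (level[k - 1] * count[k - 1] + level[k] * count[k]) /
                        (count[k - 1] + count[k]);
        count[k - 1] += count[k];
        level[k - 1] = merged;
        --k;
      }
      ++k;
    }
    int t = 0;
    for (int b = 0; b < k; ++b)
      for (int c = 0; c < count[b]; ++c) base[t++] = level[b];
    // ceiling-aware backward cap, then forward raise: guarantees a
    // feasible start (0 <= m_1, increments >= min_inc, m_T <= ceiling)
    for (int i = T - 1; i >= 0; --i)
      base[i] = std::min(base[i], ceiling - (T - 1 - i) * min_inc);
    base[0] = std::max(base[0], 0.0);
    for (int i = 1; i < T; ++i) base[i] = std::max(base[i], base[i - 1] + min_inc);
  }

  for (int w = 0; w < n_walkers; ++w) {
    std::vector<double> traj(T);
    std::vector<int> idx(T);
    if (grid_mode) {
      // nearest strictly increasing level sequence to the data
      for (int t = 0; t < T; ++t) {
        int best = 0;
        double bd = std::abs(grid_levels[0] - rho[t]);
        for (int l = 1; l < L; ++l) {
          double d = std::abs(grid_levels[l] - rho[t]);
          if (d < bd) { bd = d; best = l; }
        }
        idx[t] = best;
      }
      for (int t = 1; t < T; ++t) idx[t] = std::max(idx[t], idx[t - 1] + 1);
      for (int t = T - 1; t >= 0; --t) {
        int cap = L - 1 - (T - 1 - t);
        if (idx[t] > cap) idx[t] = cap;
      }
      for (int t = 1; t < T; ++t) idx[t] = std::max(idx[t], idx[t - 1] + 1);
      // walker-specific jitter: random feasible single-site moves
      for (int j = 0; j < 3 * w; ++j) {
        int t = (int)(unif(rng) * T); if (t >= T) t = T - 1;
        int lo = (t == 0) ? 0 : idx[t - 1] + 1;
        int hi = (t == T - 1) ? L - 1 : idx[t + 1] - 1;
        if (hi > lo) idx[t] = lo + (int)(unif(rng) * (hi - lo + 1));
      }
      for (int t = 0; t < T; ++t) traj[t] = grid_levels[idx[t]];
    } else {
      double amp = 0.02 * ceiling * (w + 1) / n_walkers;
      for (int t = 0; t < T; ++t)
        traj[t] = base[t] + amp * gauss(rng);
      for (int t = T - 1; t >= 0; --t)
        traj[t] = std::min(traj[t], ceiling - (T - 1 - t) * min_inc);
      traj[0] = std::max(traj[0], 0.0);
      for (int t = 1; t < T; ++t)
        traj[t] = std::max(traj[t], traj[t - 1] + min_inc);
      // guard against accumulated floating error above the ceiling
      if (traj[T - 1] > ceiling) traj[T - 1] = ceiling;
    }

    double step = init_step;
    int max_jump = std::max(1, L / 8);

    // retained-sample schedule: evenly spaced over post-burn-in steps
    std::vector<int> keep_at(keep_w[w]);
    for (int k = 0; k < keep_w[w]; ++k)
      keep_at[k] = burn + (int)std::floor((k + 0.5) * (double)post / keep_w[w]);
    int next_keep = 0;

    for (int it = 0; it < per_chain; ++it) {
      int j = (int)(unif(rng) * T); if (j >= T) j = T - 1;
      bool accept = false;
      if (grid_mode) {
        int jump = 1 + (int)(unif(rng) * max_jump);
        if (jump > max_jump) jump = max_jump;
        int cand = idx[j] + (unif(rng) < 0.5 ? -jump : jump);
        int lo = (j == 0) ? 0 : idx[j - 1] + 1;
        int hi = (j == T - 1) ? L - 1 : idx[j + 1] - 1;
        if (cand >= lo && cand <= hi) {
          double dll = loglik_point(grid_levels[cand], rho[j], sigma[j]) -
                       loglik_point(traj[j], rho[j], sigma[j]);
          if (dll >= 0.0 || unif(rng) < std::exp(dll)) {
            idx[j] = cand;
            traj[j] = grid_levels[cand];
            accept = true;
          }
        }
      } else {
        double cand = traj[j] + step * gauss(rng);
        double lo = (j == 0) ? 0.0 : traj[j - 1] + min_inc;
        double hi = (j == T - 1) ? ceiling : traj[j + 1] - min_inc;
        if (cand >= lo && cand <= hi) {
          double dll = loglik_point(cand, rho[j], sigma[j]) -
                       loglik_point(traj[j], rho[j], sigma[j]);
          if (dll >= 0.0 || unif(rng) < std::exp(dll)) {
            traj[j] = cand;
            accept = true;
          }
        }
        // Robbins-Monro step adaptation during burn-in only
        if (it < burn) {
          double gamma = 1.0 / std::pow(it + 1.0, 0.6);
          step *= std::exp(gamma * ((accept ? 1.0 : 0.0) - target_acceptance));
          double cap = ceiling;
          if (step > cap) step = cap;
          if (step < 1e-8) step = 1e-8;
        }
      }
      if (it >= burn) {
        n_prop += 1;
        if (accept) n_acc += 1;
        while (next_keep < keep_w[w] && keep_at[next_keep] == it) {
          for (int t = 0; t < T; ++t) samples(out_row, t) = traj[t];
          ++out_row;
          ++next_keep;
        }
      }
    }
  }

  return List::create(
    _["samples"] = samples,
    _["acceptance_rate"] = n_prop > 0 ? (double)n_acc / (double)n_prop : NA_REAL,
    _["n_total_samples"] = per_chain * n_walkers
  );
}
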