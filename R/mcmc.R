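#' Per-pixel measurement series in standardized coordinates
#'
#' One standardized pixel location observed across the ontogenetic series:
#' a strictly increasing grid of size-modeled ages and the measured density
#' at that location in each specimen where the pixel exists.
#'
#' @param times Size-modeled ages, days. Must be strictly increasing; use
#'   [jitter_ties()] first if re-assigned ages tie.
#' @param rho Measured densities, g/cm^3, one per time.
#' @param sigma Per-measurement density error, g/cm^3; scalar or vector.
#'   The default is 5% of the reference maximum density (2.62 g/cm^3) --
#'   a constant error, so that near-zero early densities are not treated
#'   as implausibly precise.
#' @param present Logical vector: does the pixel exist in that specimen?
#' @param location Optional `(EDJ distance bin, depth bin)` coordinates.
#' @return A `pixel_series` object.
#' @export
pixel_series <- function(times, rho, sigma = 0.05 * 2.62, present = NULL,
                         location = c(NA_real_, NA_real_)) {
  present <- present %||% rep(TRUE, length(times))
  stopifnot(length(rho) == length(times), length(present) == length(times))
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing (see jitter_ties())",
         call. = FALSE)
  }
  sigma <- rep_len(sigma, length(times))
  if (any(sigma[present] <= 0)) stop("sigma must be positive", call. = FALSE)
  structure(list(times = times, rho = rho, sigma = sigma, present = present,
                 location = location),
            class = "pixel_series")
}

#' Break ties in size-modeled ages deterministically
#'
#' Adds `1e-6 * rank` days within each group of tied ages so that the time
#' grid is strictly increasing, as required by the minimum-increment
#' constraint.
#'
#' @param times Sorted ages, days.
#' @return Strictly increasing ages.
#' @export
jitter_ties <- function(times) {
  stopifnot(!is.unsorted(times))
  rank_in_tie <- unlist(lapply(rle(times)$lengths, seq_len)) - 1
  times + 1e-6 * rank_in_tie
}

#' Gaussian log-likelihood of a mineralization trajectory
#'
#' `sum_t -(rho_m - rho_d)^2 / (2 sigma_t^2)` over specimens where the
#' pixel is present; absent specimens contribute 0.
#'
#' @param traj Modeled densities on the series' time grid.
#' @param series A [pixel_series()].
#' @return Log-likelihood (<= 0).
#' @export
log_lik_trajectory <- function(traj, series) {
  stopifnot(inherits(series, "pixel_series"))
  if (length(traj) != length(series$times)) {
    stop("trajectory length does not match the series' time grid",
         call. = FALSE)
  }
  p <- series$present
  -sum((traj[p] - series$rho[p])^2 / (2 * series$sigma[p]^2))
}

#' Symmetric single-site proposal
#'
#' Perturbs one uniformly chosen time point of the trajectory by a Gaussian
#' step. Feasibility (monotonicity, minimum increment, ceiling) is the
#' caller's concern: an infeasible candidate receives acceptance
#' probability 0 under the flat prior.
#'
#' @param traj Current trajectory.
#' @param step_scale Gaussian step standard deviation, g/cm^3.
#' @return The candidate trajectory.
#' @export
propose_trajectory <- function(traj, step_scale) {
  j <- sample.int(length(traj), 1)
  traj[j] <- traj[j] + rnorm(1, 0, step_scale)
  traj
}

#' Check the monotone minimum-increment constraint
#'
#' @param traj Trajectory values.
#' @param min_increment Minimum density increment per time interval,
#'   g/cm^3.
#' @param density_ceiling Upper bound on density, g/cm^3.
#' @return `TRUE` if the trajectory is feasible.
#' @export
is_monotone_feasible <- function(traj, min_increment = 1e-5,
                                 density_ceiling = 1.05 * 2.62) {
  # 1e-12/1e-9 guards absorb floating accumulation over long trajectories
  traj[1] >= 0 && traj[length(traj)] <= density_ceiling + 1e-9 &&
    (length(traj) < 2 || all(diff(traj) >= min_increment - 1e-12))
}

#' Sample monotone mineralization trajectories for one pixel
#'
#' Metropolis-Hastings sampling of the posterior over density trajectories
#' for a single standardized pixel: Gaussian likelihood
#' (see [log_lik_trajectory()]), flat prior over the set of trajectories
#' that are non-decreasing with at least `min_increment` g/cm^3 per time
#' interval and bounded by `density_ceiling`. Independent walkers start
#' from jittered isotonic regressions of the data; the single-site Gaussian
#' step is tuned towards `target_acceptance` by Robbins-Monro adaptation
#' during burn-in only (frozen afterwards, preserving detailed balance),
#' and the retained trajectories are pooled evenly across walkers by
#' uniform thinning of the post-burn-in samples.
#'
#' @param series A [pixel_series()] with at least 2 present specimens.
#' @param n_samples Total Metropolis-Hastings samples across walkers.
#' @param n_walkers Number of independent chains.
#' @param n_keep Number of retained trajectories.
#' @param seed Integer seed (the sampler has its own RNG stream; results
#'   are bit-reproducible for a given seed).
#' @param burn_in_frac Fraction of each chain discarded as burn-in.
#' @param target_acceptance Acceptance rate targeted during adaptation.
#' @param min_increment Minimum density increment per interval, g/cm^3.
#' @param density_ceiling Upper density bound, g/cm^3 (default 5% above
#'   the 2.62 reference maximum).
#' @param init_step Initial proposal step, g/cm^3.
#' @param grid_levels Optional vector of discrete density levels. When
#'   given, the sampler moves on this grid with a symmetric level-jump
#'   proposal (feasible trajectories are then strictly increasing level
#'   sequences), which makes it directly comparable to the exhaustive
#'   enumeration oracle [enumerate_trajectory_posterior()].
#' @return A `trajectory_posterior`: `samples` (matrix, `n_keep` rows, one
#'   column per present time), `times` (present times), `acceptance_rate`,
#'   `n_total_samples`, `n_walkers`, `seed`, `present`, `location`;
#'   or an unusable marker (`usable = FALSE`) when fewer than 2 specimens
#'   contain the pixel.
#' @export
sample_pixel <- function(series, n_samples = 150000, n_walkers = 4,
                         n_keep = 100, seed = 1L, burn_in_frac = 0.5,
                         target_acceptance = 0.25, min_increment = 1e-5,
                         density_ceiling = 1.05 * 2.62,
                         init_step = 0.05 * 2.62, grid_levels = NULL) {
  stopifnot(inherits(series, "pixel_series"))
  p <- series$present
  if (sum(p) < 2) {
    return(structure(list(usable = FALSE, location = series$location,
                          present = p, times = series$times),
                     class = "trajectory_posterior"))
  }
  res <- mh_sample_pixel_cpp(
    series$rho[p], series$sigma[p],
    as.integer(n_samples), as.integer(n_walkers), as.integer(n_keep),
    min_increment, density_ceiling, burn_in_frac, target_acceptance,
    init_step, as.double(seed),
    if (is.null(grid_levels)) numeric(0) else as.numeric(grid_levels)
  )
  structure(
    list(samples = res$samples, times = series$times[p],
         acceptance_rate = res$acceptance_rate,
         n_total_samples = res$n_total_samples, n_walkers = n_walkers,
         seed = seed, present = p, location = series$location,
         usable = TRUE, min_increment = min_increment,
         density_ceiling = density_ceiling),
    class = "trajectory_posterior"
  )
}

#' @export
print.trajectory_posterior <- function(x, ...) {
  if (!isTRUE(x$usable)) {
    cat("Unusable pixel (fewer than 2 present specimens)\n")
    return(invisible(x))
  }
  cat(sprintf("Monotone trajectory posterior: %d retained samples on %d times\n",
              nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  %d walkers, %d total samples, acceptance %.2f\n",
              x$n_walkers, x$n_total_samples, x$acceptance_rate))
  invisible(x)
}

#' Exhaustive posterior over monotone trajectories on a density grid
#'
#' Brute-force reference for the Metropolis-Hastings sampler on small
#' instances: enumerates every strictly increasing sequence of density
#' levels (one per time point), weights each by the Gaussian likelihood,
#' and returns exact marginal posteriors. Independent of the sampler code
#' path.
#'
#' @param series A [pixel_series()] (all-present).
#' @param levels Discrete density levels (sorted ascending).
#' @return A list: `marginals` (matrix, times x levels), `levels`,
#'   `log_weights` and `paths` (level-index matrix, one row per
#'   trajectory).
#' @export
enumerate_trajectory_posterior <- function(series, levels) {
  stopifnot(inherits(series, "pixel_series"), all(series$present))
  T_ <- length(series$times)
  L <- length(levels)
  stopifnot(L >= T_)
  paths <- t(utils::combn(L, T_))  # each row: strictly increasing indices
  ll <- apply(paths, 1, function(ix) {
    -sum((levels[ix] - series$rho)^2 / (2 * series$sigma^2))
  })
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  marg <- matrix(0, T_, L)
  for (t in seq_len(T_)) {
    for (r in seq_len(nrow(paths))) {
      marg[t, paths[r, t]] <- marg[t, paths[r, t]] + w[r]
    }
  }
  list(marginals = marg, levels = levels, log_weights = ll, paths = paths)
}

#' Marginal level frequencies of retained grid-mode samples
#'
#' @param post A `trajectory_posterior` sampled with `grid_levels`.
#' @param levels The density levels used.
#' @return Matrix (times x levels) of sample frequencies.
#' @export
posterior_level_frequencies <- function(post, levels) {
  s <- post$samples
  marg <- matrix(0, ncol(s), length(levels))
  for (t in seq_len(ncol(s))) {
    ix <- vapply(s[, t], function(v) which.min(abs(levels - v)), integer(1))
    tab <- tabulate(ix, nbins = length(levels))
    marg[t, ] <- tab / sum(tab)
  }
  marg
}

#' Build a standardized pixel stack from flattened sections
#'
#' Aligns a series of flattened sections on a common (EDJ distance bin x
#' depth bin) grid, giving each standardized pixel its measured density per
#' specimen and a presence mask. Depth is re-standardized against the
#' mature enamel thickness: each section's depth axis spans its *current*
#' surface, so the stack maps every specimen's profile onto the final
#' thickness at that EDJ position (the maximum observed across the
#' series). Depths not yet deposited in a young specimen are recorded as
#' absent, which is what lets the model resolve the appositional lag in
#' mineral arrival at outer enamel.
#'
#' @param flats List of `flattened_enamel` objects (same `edj_bin_mm` and
#'   depth binning).
#' @param records Tibble with one row per flat, including `t_m`
#'   (size-modeled age, days) in the same order as `flats`.
#' @return A `pixel_stack`: `densities` (array specimens x distance bins x
#'   depth bins, NA = absent), `times` (strictly increasing after tie
#'   jitter), `x_mm`, `depth_rel`, `records`.
#' @export
build_pixel_stack <- function(flats, records) {
  stopifnot(length(flats) == nrow(records), !is.null(records$t_m))
  ord <- order(records$t_m)
  flats <- flats[ord]
  records <- records[ord, , drop = FALSE]
  bin <- flats[[1]]$edj_bin_mm
  nd <- flats[[1]]$n_depth_bins
  depth_centers <- flats[[1]]$depth_rel
  n_x <- max(vapply(flats, function(f) {
    max(round(f$arc_mm / bin)) + 1
  }, numeric(1)))
  n_s <- length(flats)

  # per-specimen current thickness on the common distance grid
  thick <- matrix(NA_real_, n_s, n_x)
  dens_cur <- array(NA_real_, c(n_s, n_x, nd))
  for (i in seq_len(n_s)) {
    f <- flats[[i]]
    stopifnot(f$n_depth_bins == nd)
    ix <- round(f$arc_mm / bin) + 1
    keep <- !duplicated(ix)
    thick[i, ix[keep]] <- f$thickness_mm[keep]
    dens_cur[i, ix[keep], ] <- f$densities[keep, ]
  }
  # mature (final) thickness per position: the largest ever observed
  h_final <- apply(thick, 2, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })

  arr <- array(NA_real_, c(n_s, n_x, nd))
  for (i in seq_len(n_s)) {
    for (ix in seq_len(n_x)) {
      w <- thick[i, ix]
      if (is.na(w) || is.na(h_final[ix]) || w <= 0) next
      prof <- dens_cur[i, ix, ]
      ok <- is.finite(prof)
      if (sum(ok) < 2) next
      abs_d <- depth_centers * h_final[ix]
      formed <- abs_d <= w + 0.25 * bin
      if (!any(formed)) next
      arr[i, ix, formed] <- approx(depth_centers[ok] * w, prof[ok],
                                   xout = abs_d[formed], rule = 2)$y
    }
  }
  times <- records$t_m
  # deterministic tie-breaking jitter so the grid is strictly increasing
  r <- unlist(lapply(rle(times)$lengths, seq_len)) - 1
  times <- times + 1e-6 * r
  structure(
    list(densities = arr, times = times,
         x_mm = (seq_len(n_x) - 0.5) * bin,
         depth_rel = flats[[1]]$depth_rel, edj_bin_mm = bin,
         records = records),
    class = "pixel_stack"
  )
}

#' Sample monotone trajectories for every pixel of a stack
#'
#' Runs [sample_pixel()] independently for each standardized pixel with at
#' least 2 present specimens. Pixels are processed in a stable order
#' (distance-bin major, then depth bin), and each draws its own seed
#' deterministically from the master seed, so the whole run is
#' reproducible.
#'
#' @param stack A [build_pixel_stack()] result.
#' @param n_samples,n_walkers,n_keep,seed,... Passed to [sample_pixel()].
#' @param sigma Per-measurement error, g/cm^3.
#' @param progress Print progress every N pixels (0 = silent).
#' @return A `pixel_posteriors` object: `posteriors` (list), `index`
#'   (tibble: pixel, x_bin, depth_bin, x_mm, depth_rel, n_present),
#'   `times`, `records`, `seed`.
#' @export
run_all_pixels <- function(stack, n_samples = 150000, n_walkers = 4,
                           n_keep = 100, seed = 1L, sigma = 0.05 * 2.62,
                           progress = 0, ...) {
  stopifnot(inherits(stack, "pixel_stack"))
  n_x <- dim(stack$densities)[2]
  nd <- dim(stack$densities)[3]
  posteriors <- list()
  rows <- list()
  pix <- 0L
  for (ix in seq_len(n_x)) {
    for (id in seq_len(nd)) {
      rho <- stack$densities[, ix, id]
      present <- !is.na(rho)
      if (sum(present) < 2) next
      pix <- pix + 1L
      rho_f <- rho
      rho_f[!present] <- 0
      ser <- pixel_series(stack$times, rho_f, sigma = sigma,
                          present = present, location = c(ix, id))
      pseed <- (as.double(seed) * 1000003 + 7919 * pix) %% 2147483647
      posteriors[[pix]] <- sample_pixel(ser, n_samples = n_samples,
                                        n_walkers = n_walkers,
                                        n_keep = n_keep, seed = pseed, ...)
      rows[[pix]] <- tibble::tibble(pixel = pix, x_bin = ix, depth_bin = id,
                                    x_mm = stack$x_mm[ix],
                                    depth_rel = stack$depth_rel[id],
                                    n_present = sum(present))
      if (progress > 0 && pix %% progress == 0) {
        message(sprintf("sampled %d pixels", pix))
      }
    }
  }
  structure(
    list(posteriors = posteriors, index = dplyr::bind_rows(rows),
         times = stack$times, records = stack$records, seed = seed),
    class = "pixel_posteriors"
  )
}
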