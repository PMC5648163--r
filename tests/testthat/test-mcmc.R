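test_that("the trajectory log-likelihood matches hand-evaluated cases", {
  s <- pixel_series(times = c(0, 10, 20), rho = c(1, 1.5, 2), sigma = 0.131)
  expect_equal(log_lik_trajectory(c(1, 1.5, 2), s), 0)

  s1 <- pixel_series(times = 0, rho = 1, sigma = 0.2)
  expect_equal(log_lik_trajectory(1.2, s1), -0.5)

  # residuals (sigma, 2*sigma, 0): -(1/2 + 4/2 + 0) = -2.5, summed by hand
  s3 <- pixel_series(times = c(0, 10, 20), rho = c(1, 1.5, 2), sigma = 0.1)
  expect_equal(log_lik_trajectory(c(1.1, 1.7, 2), s3), -2.5)

  # absent specimens contribute nothing
  s4 <- pixel_series(times = c(0, 10, 20), rho = c(9, 1.5, 2), sigma = 0.1,
                     present = c(FALSE, TRUE, TRUE))
  expect_equal(log_lik_trajectory(c(0, 1.5, 2), s4), 0)
  expect_error(log_lik_trajectory(c(1, 2), s), "length")
})

test_that("proposals are single-site and constraint checking is strict", {
  traj <- c(0.5, 1.0, 1.5)
  expect_identical(propose_trajectory(traj, 0), traj)
  set.seed(1)
  cand <- propose_trajectory(traj, 0.3)
  expect_equal(sum(cand != traj), 1L)
  expect_true(is_monotone_feasible(c(0.5, 1.0, 1.5)))
  expect_false(is_monotone_feasible(c(0.5, 1.5, 1.0)))
  expect_false(is_monotone_feasible(c(0.5, 0.5, 1.0)))   # increment < 1e-5
  expect_false(is_monotone_feasible(c(0.5, 1.0, 3.0)))   # above ceiling
  expect_false(is_monotone_feasible(c(-0.1, 1.0, 1.5))) # below zero
})

test_that("sampling is bit-reproducible and tuned into a sane acceptance band", {
  set.seed(3)
  rho <- sort(runif(12, 0.3, 2.6))
  ser <- pixel_series(times = seq(0, 110, by = 10), rho = rho, sigma = 0.131)
  p1 <- sample_pixel(ser, n_samples = 30000, seed = 9)
  p2 <- sample_pixel(ser, n_samples = 30000, seed = 9)
  expect_identical(p1$samples, p2$samples)
  expect_gte(p1$acceptance_rate, 0.1)
  expect_lte(p1$acceptance_rate, 0.5)
  expect_equal(nrow(p1$samples), 100L)
  # every retained trajectory obeys the monotone minimum-increment rule
  expect_true(all(apply(p1$samples, 1, is_monotone_feasible)))
})

test_that("near-noise-free monotone data dominates the posterior", {
  ser <- pixel_series(times = c(0, 20, 40, 60), rho = c(0.5, 1.0, 1.8, 2.4),
                      sigma = 0.01)
  post <- sample_pixel(ser, n_samples = 60000, seed = 2)
  expect_true(all(abs(colMeans(post$samples) - ser$rho) < 2 * 0.01))
})

test_that("the monotone constraint binds on decreasing data", {
  ser <- pixel_series(times = c(0, 20, 40), rho = c(2.4, 1.5, 0.5),
                      sigma = 0.05)
  post <- sample_pixel(ser, n_samples = 40000, seed = 4)
  expect_true(all(apply(post$samples, 1, is_monotone_feasible)))
  # the fit cannot follow the data downwards: large residual misfit remains
  expect_lt(log_lik_trajectory(colMeans(post$samples), ser), -100)
})

test_that("grid-mode marginals match the exhaustive enumeration oracle", {
  levels <- seq(0, 2.75, length.out = 20)
  ser <- pixel_series(times = c(0, 30, 60), rho = c(0.6, 1.4, 2.3),
                      sigma = 0.131)
  en <- enumerate_trajectory_posterior(ser, levels)
  gs <- sample_pixel(ser, n_samples = 200000, n_keep = 5000, seed = 3,
                     grid_levels = levels)
  fr <- posterior_level_frequencies(gs, levels)
  tv <- vapply(seq_along(ser$times), function(t) {
    0.5 * sum(abs(fr[t, ] - en$marginals[t, ]))
  }, numeric(1))
  expect_lt(max(tv), 0.05)
})

test_that("continuous sampling agrees with a fine-grid enumeration on plateaus", {
  # four equal observations: the flat monotone prior spreads the marginals
  # like order statistics; the sampler must reproduce that exactly
  levels <- seq(2.1, 2.751, length.out = 36)
  ser <- pixel_series(times = seq(0, 30, by = 10), rho = rep(2.62, 4),
                      sigma = 0.131)
  en <- enumerate_trajectory_posterior(ser, levels)
  em <- as.vector(en$marginals %*% levels)
  post <- sample_pixel(ser, n_samples = 400000, n_keep = 4000, seed = 2,
                       density_ceiling = 2.751)
  expect_lt(max(abs(colMeans(post$samples) - em)), 0.03)
})

test_that("credible bands cover the truth in the active phase (anti-conservative on plateaus)", {
  p <- default_params()
  ages <- synthetic_series_ages(45)
  set.seed(7)
  cov_act <- 0L; n_act <- 0L; cov_plat <- 0L; n_plat <- 0L
  for (rep in 1:15) {
    x <- runif(1, 2, 36); d <- runif(1, 0.05, 0.95)
    truth <- truth_density(x, d, ages, p)
    rho <- truth * (1 + 0.05 * pmin(pmax(rnorm(45), -4), 4))
    present <- rho > 0
    if (sum(present) < 2) next
    ser <- pixel_series(jitter_ties(ages), pmax(rho, 0), sigma = 0.131,
                        present = present)
    post <- sample_pixel(ser, n_samples = 150000, seed = rep)
    qs <- apply(post$samples, 2, quantile, c(0.05, 0.95))
    tr <- truth[present]
    covered <- tr >= qs[1, ] - 1e-9 & tr <= qs[2, ] + 1e-9
    active <- tr < 0.995 * p$max_density
    cov_act <- cov_act + sum(covered[active]); n_act <- n_act + sum(active)
    cov_plat <- cov_plat + sum(covered[!active]); n_plat <- n_plat + sum(!active)
  }
  expect_gte(cov_act / n_act, 0.6)
  expect_gt(cov_act / n_act, cov_plat / n_plat)
})

test_that("pixels observed in fewer than two specimens are flagged unusable", {
  ser <- pixel_series(times = c(0, 10, 20), rho = c(0, 0, 1), sigma = 0.1,
                      present = c(FALSE, FALSE, TRUE))
  post <- sample_pixel(ser, n_samples = 1000, seed = 1)
  expect_false(post$usable)
})

test_that("specimen input order does not change the posterior", {
  set.seed(11)
  times <- seq(0, 100, by = 10)
  rho <- sort(runif(11, 0.3, 2.5))
  perm <- sample(11)
  ord <- order(times[perm])
  ser1 <- pixel_series(times, rho, sigma = 0.131)
  ser2 <- pixel_series(times[perm][ord], rho[perm][ord], sigma = 0.131)
  expect_identical(sample_pixel(ser1, n_samples = 20000, seed = 6)$samples,
                   sample_pixel(ser2, n_samples = 20000, seed = 6)$samples)
})

test_that("a toy stack yields complete, reproducible per-pixel posteriors", {
  run <- fixture_series_run()
  posts <- run$posteriors$posteriors
  expect_true(all(vapply(posts, function(p) nrow(p$samples) == 100L,
                         logical(1))))
  # stable order and deterministic seeds: re-sampling one pixel reproduces it
  k <- 25L
  idx <- run$posteriors$index[k, ]
  stack <- run$stack
  rho <- stack$densities[, idx$x_bin, idx$depth_bin]
  present <- !is.na(rho)
  rho[!present] <- 0
  ser <- pixel_series(stack$times, rho, sigma = 0.05 * 2.62,
                      present = present, location = c(idx$x_bin, idx$depth_bin))
  pseed <- (as.double(run$posteriors$seed) * 1000003 + 7919 * k) %% 2147483647
  again <- sample_pixel(ser, n_samples = 30000, n_walkers = 4, n_keep = 100,
                        seed = pseed)
  expect_identical(again$samples, posts[[k]]$samples)
})
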