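# hand-built posteriors: 3 specimens, 4 pixels, 5 retained samples
toy_posteriors <- function() {
  times <- c(10, 50, 90)
  mk <- function(present, base) {
    nt <- sum(present)
    samples <- matrix(rep(base[seq_len(nt)], each = 5), 5, nt) +
      outer(seq(0, 0.04, length.out = 5), rep(1, nt))
    structure(list(samples = samples, times = times[present],
                   acceptance_rate = 0.25, n_total_samples = 100,
                   n_walkers = 4, seed = 1, present = present,
                   location = c(NA, NA), usable = TRUE),
              class = "trajectory_posterior")
  }
  posts <- list(
    mk(c(TRUE, TRUE, TRUE), c(0.6, 1.4, 2.5)),
    mk(c(TRUE, TRUE, TRUE), c(0.7, 1.8, 2.6)),
    mk(c(FALSE, TRUE, TRUE), c(0.9, 2.0)),
    mk(c(FALSE, FALSE, TRUE), c(1.1))
  )
  structure(
    list(posteriors = posts,
         index = tibble::tibble(pixel = 1:4, x_bin = c(1, 2, 3, 4),
                                depth_bin = c(1, 1, 2, 2),
                                x_mm = c(0.1, 0.3, 0.5, 0.7),
                                depth_rel = c(0.25, 0.25, 0.75, 0.75),
                                n_present = c(3, 3, 2, 1)),
         times = times, records = NULL, seed = 7),
    class = "pixel_posteriors"
  )
}

test_that("the HDF5 model round-trips losslessly with the published schema", {
  path <- withr::local_tempfile(fileext = ".h5")
  model <- assemble_model(toy_posteriors(), path)
  expect_true(file.exists(path))
  expect_setequal(rhdf5::h5ls(path)$name,
                  c("age_mask", "ages", "locations", "pct_min_samples"))
  back <- read_model(path)
  expect_equal(back$age_mask, model$age_mask)
  expect_equal(back$ages, model$ages)
  expect_equal(back$locations, model$locations)
  expect_equal(back$pct_min_samples, model$pct_min_samples)

  # shapes: specimens x pixels; samples x pixels x specimen-ages
  expect_identical(dim(model$age_mask), c(3L, 4L))
  expect_identical(dim(model$pct_min_samples), c(5L, 4L, 3L))
  expect_identical(dim(model$locations), c(4L, 2L))

  # absent pixel-ages: mask 0 and sentinel -1
  expect_identical(model$age_mask[1, 3], 0L)
  expect_true(all(model$pct_min_samples[, 3, 1] == -1))
  expect_identical(model$age_mask[2, 1], 1L)
  # stored as percent of the reference maximum
  expect_equal(model$pct_min_samples[1, 1, 1], 0.6 / 2.62 * 100)
})

test_that("the full-scale model shape implies 336 million density estimates", {
  # shape metadata only; nothing is materialized
  expect_identical(n_density_estimates(n_pixels = 12000, n_days = 280,
                                       n_keep = 100), 336e6)
  path <- withr::local_tempfile(fileext = ".h5")
  model <- assemble_model(toy_posteriors(), path)
  expect_identical(n_density_estimates(model, n_days = 280), 4 * 280 * 5)
})

test_that("daily interpolation is exact at specimen ages and stays monotone", {
  path <- withr::local_tempfile(fileext = ".h5")
  model <- assemble_model(toy_posteriors(), path)
  daily <- interpolate_daily(model, n_days = 100, start_day = 10)
  expect_identical(dim(daily$density_pct), c(5L, 4L, 100L))
  # at an exact specimen age the stored sample value is returned
  expect_equal(daily$density_pct[, 1, which(daily$days == 50)],
               model$pct_min_samples[, 1, 2])
  # monotone along days wherever defined
  ok <- apply(daily$density_pct, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    length(v) < 2 || all(diff(v) >= -1e-9)
  })
  expect_true(all(ok))
  # a pixel with < 2 present ages is excluded
  expect_true(4L %in% daily$excluded)
})

test_that("rate fields are non-negative, telescoping, and zero for constant input", {
  path <- withr::local_tempfile(fileext = ".h5")
  model <- assemble_model(toy_posteriors(), path)
  daily <- interpolate_daily(model, n_days = 100, start_day = 10)
  rf <- rate_field(daily)
  expect_gte(min(rf$rates, na.rm = TRUE), 0)
  for (j in 1:3) {
    expect_equal(sum(rf$rates[j, ]),
                 rf$summary[j, ncol(rf$summary)] - rf$summary[j, 1],
                 tolerance = 1e-9)
  }
  # constant trajectory -> zero rate
  flat <- daily
  flat$density_pct[] <- 50
  rf0 <- rate_field(flat)
  expect_true(all(rf0$rates == 0))
})

test_that("time averaging is zero for step trajectories and ordered by depth", {
  # a pixel that mineralizes instantaneously to full density between
  # consecutive daily ages
  tp <- toy_posteriors()
  tp$times <- c(10, 11, 90)
  tp$posteriors <- tp$posteriors[1]
  tp$posteriors[[1]]$times <- tp$times
  tp$posteriors[[1]]$samples <- matrix(c(1e-3, 2.62, 2.62), 5, 3,
                                       byrow = TRUE)
  tp$index <- tp$index[1, ]
  path <- withr::local_tempfile(fileext = ".h5")
  model <- assemble_model(tp, path)
  daily <- interpolate_daily(model, n_days = 120, start_day = 10)
  tam <- time_averaging_map(daily)
  expect_lt(tam$days_averaged[tam$pixel == 1], 1.5)

  # generator series: inner enamel averages longer than outer enamel,
  # and a mid-crown mid-depth location averages ~lag + maturation duration
  run <- fixture_series_run()
  tam2 <- time_averaging_map(run$daily)
  bands <- time_averaging_by_band(tam2, n_depth_bins = 10)
  expect_gt(bands$mean_days[bands$band == "inner"],
            bands$mean_days[bands$band == "outer"])
  idx <- run$posteriors$index
  mid <- tam2[abs(idx$x_mm[match(tam2$pixel, idx$pixel)] - 19) < 2 &
                tam2$depth_bin %in% 5:6 & !tam2$incomplete, ]
  expect_lt(abs(mean(mid$days_averaged) - 77.5), 15)
})

test_that("animation frames respect the blur settings", {
  # rate field away from the grid borders so blur mass is conserved
  n_pix <- 5
  rates <- structure(
    list(rates = matrix(runif(n_pix * 30), n_pix, 30),
         days = seq_len(30),
         locations = cbind(5:9, c(5, 6, 7, 6, 5)),
         summary = NULL, summary_days = NULL, index = NULL,
         statistic = "mean"),
    class = "rate_field"
  )
  dir0 <- withr::local_tempdir()
  raw <- export_animation_frames(rates, file.path(dir0, "raw"),
                                 sigma_xy = 0, sigma_t = 0,
                                 grid_dims = c(14, 12))
  blur <- export_animation_frames(rates, file.path(dir0, "blur"),
                                  sigma_xy = 1, sigma_t = 8,
                                  grid_dims = c(14, 12))
  expect_length(raw$files, 30L)
  expect_true(all(file.exists(blur$files)))
  # sigma 0 reproduces the unblurred field exactly
  for (j in seq_len(n_pix)) {
    expect_equal(raw$frames[rates$locations[j, 1], rates$locations[j, 2], ],
                 rates$rates[j, ])
  }
  # interior blur conserves total rate mass within 1%
  expect_equal(sum(blur$frames), sum(raw$frames), tolerance = 0.01)
})

test_that("sparse series carry an intrinsic chord bias in completion times", {
  # linear interpolation between bracketing specimen ages lies below the
  # concave upper ramp, so 85% crossings are late even with noise-free
  # data; this floor dominates completion-time error in small series
  p <- default_params()
  chord_rms <- function(ages) {
    days <- seq(min(ages), max(ages), by = 1)
    set.seed(31)
    err <- c()
    for (k in 1:150) {
      x <- runif(1, 2, 36); d <- runif(1, 0.05, 0.95)
      tc <- truth_completion_day(p, x, d)
      if (is.na(tc)) next
      rr <- truth_density(x, d, ages, p)
      if (max(rr) < 0.85 * p$max_density || sum(rr > 0) < 2) next
      yi <- approx(ages, rr, xout = days)$y
      hit <- min(which(yi >= 0.85 * p$max_density))
      if (hit == 1) next
      cross <- days[hit - 1] + (0.85 * p$max_density - yi[hit - 1]) /
        (yi[hit] - yi[hit - 1])
      err <- c(err, cross - tc)
    }
    sqrt(mean(err^2))
  }
  floor12 <- chord_rms(synthetic_series_ages(12, 510) + 20)
  floor45 <- chord_rms(synthetic_series_ages(45))
  expect_gt(floor12, 10)    # a 12-specimen series cannot beat ~10 d RMS
  expect_lt(floor45, 3)     # a 45-specimen series nearly removes the bias
})

test_that("retained model samples are monotone at present ages", {
  run <- fixture_series_run()
  model <- run$model
  n_ok <- 0L; n_tot <- 0L
  for (j in seq_len(dim(model$pct_min_samples)[2])) {
    present <- model$age_mask[, j] == 1
    if (sum(present) < 2) next
    s <- model$pct_min_samples[, j, present]
    mono <- apply(s, 1, function(v) all(diff(v) >= -1e-9))
    n_ok <- n_ok + sum(mono); n_tot <- n_tot + length(mono)
  }
  expect_identical(n_ok, n_tot)
})
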