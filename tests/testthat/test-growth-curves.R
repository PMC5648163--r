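test_that("the forward curve has the expected analytic anchors", {
  p <- growth_curve_params(20, 0.01, 100, 38)
  expect_equal(extension_length(100, p), 18)           # t = o -> el_max - a
  expect_equal(extension_length(1e7, p), 38, tolerance = 1e-9)
  expect_equal(extension_age(18, p), 100)              # inverse at midpoint
})

test_that("forward and inverse curves are mutual inverses on random draws", {
  set.seed(123)
  for (i in 1:1000) {
    p <- growth_curve_params(a = runif(1, 5, 40), s = runif(1, 0.002, 0.03),
                             o = runif(1, -50, 200), el_max = runif(1, 10, 50))
    t <- runif(1, p$o - 2 / p$s, p$o + 2 / p$s)
    expect_lt(abs(extension_age(extension_length(t, p), p) - t), 1e-9)
  }
})

test_that("the closed-form inverse matches a bisection oracle", {
  p <- growth_curve_params(20, 0.01, 100, 38)
  e_l <- 30
  # independent oracle: invert the forward curve by bisection to 1e-9
  lo <- -1000; hi <- 5000
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (extension_length(mid, p) < e_l) lo <- mid else hi <- mid
  }
  expect_lt(abs(extension_age(e_l, p) - (lo + hi) / 2), 1e-6)
  expect_error(extension_age(38.5, p), "range")
})

test_that("the fitter recovers noise-free generating parameters", {
  true <- default_extension()
  ages <- synthetic_series_ages(45)
  fit <- fit_growth_curve(
    tibble::tibble(age_days = ages,
                   position_mm = extension_length(ages, true)),
    el_max = true$el_max, initiation_day = -49
  )
  expect_lt(abs(fit$params$a / true$a - 1), 1e-4)
  expect_lt(abs(fit$params$s / true$s - 1), 1e-4)
  expect_lt(abs(fit$params$o / true$o - 1), 1e-4)
  expect_lt(fit$rss, 1e-10)
  # broom-style accessors
  td <- tidy(fit)
  expect_identical(td$term, c("a", "s", "o", "el_max"))
  expect_equal(glance(fit)$n, 45L)
})

test_that("the fitter is robust to landmark-level measurement noise", {
  true <- default_extension()
  ages <- synthetic_series_ages(45)
  pos <- extension_length(ages, true)
  ok <- 0L
  for (r in 1:30) {
    set.seed(r)
    fit <- fit_growth_curve(
      tibble::tibble(age_days = ages, position_mm = pos + 0.1 * rnorm(45)),
      el_max = true$el_max, initiation_day = -49, seed = r
    )
    re <- abs(c(fit$params$a, fit$params$s, fit$params$o) /
                c(true$a, true$s, true$o) - 1)
    if (all(re < 0.10)) ok <- ok + 1L
  }
  expect_gte(ok, 28L)
})

test_that("underdetermined fits are rejected", {
  expect_error(
    fit_growth_curve(tibble::tibble(age_days = c(0, 100),
                                    position_mm = c(1, 10))),
    "at least 3"
  )
})

test_that("age re-assignment is a function of extension length only", {
  true <- default_extension()
  ages <- synthetic_series_ages(45)
  fit <- fit_growth_curve(
    tibble::tibble(age_days = ages,
                   position_mm = extension_length(ages, true)),
    el_max = true$el_max, initiation_day = -49
  )
  rec <- tibble::tibble(
    specimen_id = c("a", "b", "c", "d"),
    age_days = c(100, 180, 150, 500),
    e_l_mm = c(extension_length(100, fit$params), 24, 24,
               true$el_max)
  )
  out <- reassign_ages(rec, fit)
  # specimen on the curve keeps its age
  expect_equal(out$t_m[out$specimen_id == "a"], 100, tolerance = 1e-6)
  # equal lengths -> equal modeled ages regardless of chronological age
  expect_equal(out$t_m[out$specimen_id == "b"],
               out$t_m[out$specimen_id == "c"])
  # a fully grown specimen keeps its chronological age
  expect_equal(out$t_m[out$specimen_id == "d"], 500)
  expect_false(is.unsorted(out$t_m))
})

test_that("size-modeled age tracks developmental stage better than chronology", {
  true <- default_extension()
  set.seed(5)
  age <- sort(runif(45, 10, 500))
  stage <- age * rnorm(45, 1, 0.15)          # individual growth-rate jitter
  stage <- pmax(stage, 1)
  e_l <- extension_length(stage, true)
  fit <- fit_growth_curve(tibble::tibble(age_days = age, position_mm = e_l),
                          el_max = true$el_max, initiation_day = -49)
  rec <- reassign_ages(tibble::tibble(specimen_id = as.character(1:45),
                                      age_days = age, e_l_mm = e_l), fit)
  rec <- rec[order(as.integer(rec$specimen_id)), ]
  expect_gt(cor(rec$t_m, stage, method = "spearman"),
            cor(age, stage, method = "spearman"))
})

test_that("fitted extension, onset and completion curves are ordered", {
  p <- default_params()
  ages <- synthetic_series_ages(45)
  lms <- tibble::tibble(
    age_days = ages,
    e_l_mm = extension_length(ages, default_extension()),
    onset_mm = vapply(ages, function(a) truth_crossing(p, a, 0.40),
                      numeric(1)),
    completion_mm = vapply(ages, function(a) truth_crossing(p, a, 0.85),
                           numeric(1))
  )
  fits <- fit_growth_curves(lms, initiation_day = -49, n_starts = 100)
  tt <- seq(0, 540, by = 5)
  ext <- extension_length(tt, fits$extension$params)
  ons <- extension_length(tt, fits$onset$params)
  cmp <- extension_length(tt, fits$completion$params)
  expect_true(all(cmp <= ons + 0.35))
  expect_true(all(ons <= ext + 0.35))
  # extension rate peaks early: before the midpoint of the observed span
  expect_lt(fits$extension$params$o, mean(range(ages)))
})
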