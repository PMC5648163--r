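# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_params <- function() wave_model_params()

# noise-free rendered section + density map + flattened grid at one age
fixture_section <- function(age) {
  fixture(paste0("section_", age), function() {
    p <- default_params()
    sec <- render_section(p, age = age, noise_frac = 0, seed = 1)
    dm <- calibrate_section(sec, synthetic_calibration())
    fl <- suppressMessages(flatten_enamel(dm, n_depth_bins = 10))
    list(params = p, section = sec, dmap = dm, flat = fl,
         landmarks = measure_landmarks(fl))
  })
}

# full-series pipeline at the default study conditions (45 specimens),
# scaled in pixel count and chain length for test runtime
fixture_series_run <- function() {
  fixture("series_run", function() {
    p <- default_params()
    suppressWarnings(suppressMessages(run_mineralization_pipeline(
      p, synthetic_series_ages(45), n_depth_bins = 10,
      mcmc = list(n_samples = 30000), seed = 11, x_stride = 6
    )))
  })
}

# true position of the farthest 40%/85% mid-depth crossing at an age
truth_crossing <- function(params, age, frac, d = 0.5) {
  xs <- seq(0.01, params$extension$el_max - 0.01, by = 0.005)
  dd <- truth_density(xs, d, age, params)
  thr <- frac * params$max_density
  if (!any(dd >= thr)) 0 else max(xs[dd >= thr])
}

# true day a location reaches a density fraction
truth_completion_day <- function(params, x, d, frac = 0.85) {
  tt <- seq(-60, 600, by = 0.25)
  td <- truth_density(x, d, tt, params)
  thr <- frac * params$max_density
  if (!any(td >= thr)) NA_real_ else tt[min(which(td >= thr))]
}

default_extension <- function() {
  e <- default_params()$extension
  growth_curve_params(e$a, e$s, e$o, e$el_max)
}
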