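#' Parameters of the two-wave synthetic enamel growth model
#'
#' The forward simulator mimics how a ruminant molar mineralizes: a secretory
#' front advances along the enamel-dentin junction (EDJ) following an
#' integrated-Gaussian extension curve while enamel thickens by apposition,
#' depositing a partially mineralized matrix; a second, lagged maturation wave
#' then raises density to its mature maximum. Ground truth (onset/completion
#' times and the full density history at every location) is available in
#' closed form, so rendered sections can serve as oracles for the whole
#' pipeline.
#'
#' @param extension A list with elements `a` (amplitude, mm), `s` (slope,
#'   1/day), `o` (offset, days) and `el_max` (mature EDJ length, mm) for the
#'   error-function extension curve. The default describes a first molar that
#'   initiates about 49 days before birth and approaches 38 mm.
#' @param secretion_density_frac Fraction of the mature density deposited at
#'   secretion (secreted enamel carries roughly a fifth to a third of mature
#'   mineral weight). Must lie in (0, 1).
#' @param maturation_lag_cuspal Days between secretion and maturation onset
#'   at the EDJ (relative depth 0).
#' @param lag_depth_gradient Days of lag lost per unit relative depth; the
#'   pause before maturation shrinks towards the outer enamel surface. The
#'   lag is floored at 0.
#' @param maturation_duration Days from maturation onset (start of the
#'   density ramp) to maturation completion at a fixed location.
#'   Completion follows the field's landmark definition: attainment of
#'   `completion_frac` (85%) of the mature density; the remaining mineral
#'   accrues in a slow tail beyond `maturation_duration`.
#' @param completion_frac Density fraction defining maturation completion.
#' @param max_density Mature hydroxyapatite density, g/cm^3.
#' @param apposition_rate Enamel thickening rate, mm/day.
#' @param enamel_thickness Enamel thickness in mm; either a single number or
#'   a function of EDJ distance (mm).
#' @param noise_frac Relative (multiplicative) measurement noise used when
#'   rendering sections.
#' @param edj_angle_deg Angle of the EDJ relative to the image rows when a
#'   section is rendered, degrees. The secretory-front angle itself emerges
#'   from the ratio of apposition to extension rate.
#' @param ramp_shape Steepness of the logistic density ramp between
#'   maturation onset and completion (dimensionless).
#' @param seed Integer seed for rendering noise.
#'
#' @return An object of class `wave_model_params`.
#' @export
wave_model_params <- function(extension = list(a = 25, s = 0.006, o = 33.5,
                                               el_max = 38),
                              secretion_density_frac = 0.25,
                              maturation_lag_cuspal = 40,
                              lag_depth_gradient = 25,
                              maturation_duration = 50,
                              completion_frac = 0.85,
                              max_density = 2.62,
                              apposition_rate = 0.02,
                              enamel_thickness = 0.6,
                              noise_frac = 0.05,
                              edj_angle_deg = 8,
                              ramp_shape = 10,
                              seed = 1L) {
  stopifnot(
    secretion_density_frac > 0, secretion_density_frac < 1,
    maturation_lag_cuspal >= 0, lag_depth_gradient >= 0,
    maturation_duration >= 0, max_density > 0,
    completion_frac > secretion_density_frac, completion_frac <= 1,
    apposition_rate > 0, noise_frac >= 0,
    extension$a > 0, extension$s > 0, extension$el_max > 0
  )
  h <- if (is.function(enamel_thickness)) enamel_thickness else {
    stopifnot(enamel_thickness > 0)
    local({ h0 <- enamel_thickness; function(x) rep_len(h0, length(x)) })
  }
  structure(
    list(extension = extension,
         secretion_density_frac = secretion_density_frac,
         maturation_lag_cuspal = maturation_lag_cuspal,
         lag_depth_gradient = lag_depth_gradient,
         maturation_duration = maturation_duration,
         completion_frac = completion_frac,
         max_density = max_density,
         apposition_rate = apposition_rate,
         enamel_thickness = h,
         noise_frac = noise_frac,
         edj_angle_deg = edj_angle_deg,
         ramp_shape = ramp_shape,
         seed = as.integer(seed)),
    class = "wave_model_params"
  )
}

#' Grid specification for simulated ground truth
#'
#' @param pixel_size_mm Spatial resolution along the EDJ and in depth, mm.
#' @param time_step_days Temporal resolution, days.
#' @param n_depth_bins Number of relative-depth samples spanning \[0, 1\].
#' @param t_min,t_max Time range in days; `t_min = NULL` starts at crown
#'   initiation (the age at which the extension curve reaches length 0).
#' @return A list of class `truth_grid`.
#' @export
truth_grid <- function(pixel_size_mm = 0.2, time_step_days = 2,
                       n_depth_bins = 21, t_min = NULL, t_max = 540) {
  if (pixel_size_mm <= 0 || time_step_days <= 0) {
    stop("grid spacings must be positive", call. = FALSE)
  }
  stopifnot(n_depth_bins >= 3)
  structure(list(pixel_size_mm = pixel_size_mm,
                 time_step_days = time_step_days,
                 n_depth_bins = as.integer(n_depth_bins),
                 t_min = t_min, t_max = t_max),
            class = "truth_grid")
}

# --- analytic truth -------------------------------------------------------

# time at which the secretory front reaches EDJ distance x (mm);
# inverse of the extension curve, -Inf-safe at x = 0 via domain clamping
truth_extension_time <- function(x, params) {
  p <- params$extension
  extension_age(pmin(pmax(x, 1e-9), p$el_max - 1e-9),
                growth_curve_params(p$a, p$s, p$o, p$el_max))
}

# secretion onset at (x, d): front arrival plus appositional build-out
truth_secretion_time <- function(x, d, params) {
  h <- params$enamel_thickness(x)
  truth_extension_time(x, params) + d * h / params$apposition_rate
}

truth_lag <- function(d, params) {
  pmax(0, params$maturation_lag_cuspal - params$lag_depth_gradient * d)
}

truth_maturation_onset <- function(x, d, params) {
  truth_secretion_time(x, d, params) + truth_lag(d, params)
}

truth_maturation_completion <- function(x, d, params) {
  truth_maturation_onset(x, d, params) + params$maturation_duration
}

# scaled logistic ramp: exactly 0 at tau <= 0 and 1 at tau >= 1
logistic_ramp <- function(tau, k) {
  tau <- pmin(pmax(tau, 0), 1)
  lo <- stats::plogis(-k / 2)
  hi <- stats::plogis(k / 2)
  (stats::plogis(k * (tau - 0.5)) - lo) / (hi - lo)
}

# ramp time (fraction of the unit ramp) at which density reaches the
# completion landmark; maturation_duration spans onset -> completion
ramp_tau_completion <- function(params) {
  f0 <- params$secretion_density_frac
  q <- (params$completion_frac - f0) / (1 - f0)
  if (q >= 1) return(1)
  k <- params$ramp_shape
  lo <- stats::plogis(-k / 2); hi <- stats::plogis(k / 2)
  0.5 + stats::qlogis(q * (hi - lo) + lo) / k
}

#' True density at standardized locations and times
#'
#' Closed-form density (g/cm^3) of the synthetic growth model at EDJ
#' distance `x` (mm), relative depth `d` and age `t` (days). Density is 0
#' before local secretion, jumps to `secretion_density_frac * max_density`
#' at secretion, and rises along a logistic ramp to `max_density` between
#' maturation onset and completion.
#'
#' @param x,d,t Vectors (recycled to a common length) of EDJ distance (mm),
#'   relative depth in \[0,1\], and age (days).
#' @param params A [wave_model_params()] object.
#' @return Numeric vector of densities.
#' @export
truth_density <- function(x, d, t, params) {
  n <- max(length(x), length(d), length(t))
  x <- rep_len(x, n); d <- rep_len(d, n); t <- rep_len(t, n)
  t_sec <- truth_secretion_time(x, d, params)
  t_on <- t_sec + truth_lag(d, params)
  f0 <- params$secretion_density_frac
  dur <- params$maturation_duration
  frac <- if (dur > 0) {
    tau85 <- ramp_tau_completion(params)
    f0 + (1 - f0) * logistic_ramp(tau85 * (t - t_on) / dur,
                                  params$ramp_shape)
  } else {
    f0 + (1 - f0) * as.numeric(t >= t_on)
  }
  rho <- params$max_density * frac
  rho[t < t_sec] <- 0
  rho
}

#' Simulate ground-truth mineralization on a grid
#'
#' Evaluates the analytic two-wave model on an (EDJ distance x relative
#' depth x time) grid, together with per-location secretion onset,
#' maturation onset and maturation completion times.
#'
#' @param params A [wave_model_params()] object.
#' @param grid A [truth_grid()] object.
#' @return An object of class `synthetic_truth` with elements
#'   `density` (array `[x, depth, time]`), `x_mm`, `depth_rel`, `times`,
#'   `secretion_onset`, `maturation_onset`, `maturation_completion`
#'   (matrices `[x, depth]`), and `params`.
#' @export
simulate_truth <- function(params, grid = truth_grid()) {
  stopifnot(inherits(params, "wave_model_params"), inherits(grid, "truth_grid"))
  px <- grid$pixel_size_mm
  el_max <- params$extension$el_max
  x <- seq(px / 2, el_max - px / 2, by = px)
  d <- seq(0, 1, length.out = grid$n_depth_bins)
  t0 <- grid$t_min %||% truth_extension_time(0, params)
  times <- seq(t0, grid$t_max, by = grid$time_step_days)

  xd <- expand.grid(x = x, d = d)
  sec <- matrix(truth_secretion_time(xd$x, xd$d, params),
                nrow = length(x))
  onset <- sec + matrix(truth_lag(xd$d, params), nrow = length(x))
  comp <- onset + params$maturation_duration

  dens <- vapply(times, function(t) {
    matrix(truth_density(xd$x, xd$d, t, params), nrow = length(x))
  }, matrix(0, length(x), length(d)))

  structure(
    list(density = dens, x_mm = x, depth_rel = d, times = times,
         secretion_onset = sec, maturation_onset = onset,
         maturation_completion = comp, params = params),
    class = "synthetic_truth"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Render a virtual enamel section at a given age
#'
#' Projects the analytic growth model into a 16-bit grayscale image the way a
#' virtual buccal section through a scanned tooth would look: the EDJ runs at
#' `edj_angle_deg` to the image rows, formed enamel occupies the band between
#' the EDJ and the current appositional surface, grey values invert the
#' calibration line (`grey = (rho - intercept)/slope`), and multiplicative
#' Gaussian noise (sd `noise_frac * rho`, truncated at 4 sd) is applied.
#' Background pixels are grey 0; formed enamel is clamped to grey >= 1.
#'
#' @param params A [wave_model_params()] object (or a `synthetic_truth`,
#'   whose params are used).
#' @param age Age at death, days.
#' @param calib A [calibration_params()] object used to invert densities to
#'   grey values.
#' @param pixel_size_mm Rendered pixel size, mm.
#' @param noise_frac Relative noise; defaults to the generator's value. Use 0
#'   for noise-free oracles.
#' @param seed Integer seed for the rendering noise.
#' @param specimen_id,batch,molar,worn Metadata attached to the section.
#' @return A `tooth_section`: list with `pixels` (integer matrix, grey 0 =
#'   background), `pixel_size_mm` and the metadata fields.
#' @export
render_section <- function(params, age, calib = synthetic_calibration(),
                           pixel_size_mm = 0.2, noise_frac = NULL,
                           seed = 1L, specimen_id = "S1", batch = calib$batch_id,
                           molar = "M1", worn = FALSE) {
  if (inherits(params, "synthetic_truth")) params <- params$params
  stopifnot(inherits(params, "wave_model_params"))
  noise_frac <- noise_frac %||% params$noise_frac
  px <- pixel_size_mm
  el_max <- params$extension$el_max
  theta <- params$edj_angle_deg * pi / 180
  h_max <- max(params$enamel_thickness(seq(0, el_max, length.out = 101)))

  margin <- 2L
  r0 <- margin + ceiling(h_max * cos(theta) / px) + 1L
  c0 <- margin + 1L
  nr <- r0 + ceiling(el_max * sin(theta) / px) + margin
  nc <- c0 + ceiling(el_max * cos(theta) / px) + margin

  rr <- matrix(seq_len(nr) - r0, nr, nc)
  cc <- matrix(rep(seq_len(nc) - c0, each = nr), nr, nc)
  x_mm <- (rr * sin(theta) + cc * cos(theta)) * px
  depth_mm <- (-rr * cos(theta) + cc * sin(theta)) * px

  h <- matrix(params$enamel_thickness(pmin(pmax(x_mm, 0), el_max)), nr, nc)
  inside <- x_mm >= 0 & x_mm < el_max & depth_mm >= 0 & depth_mm < h
  t_ext <- matrix(NA_real_, nr, nc)
  t_ext[inside] <- truth_extension_time(x_mm[inside], params)
  formed <- inside & !is.na(t_ext) & (age >= t_ext) &
    (depth_mm <= params$apposition_rate * pmax(age - t_ext, 0))
  formed[is.na(formed)] <- FALSE

  pixels <- matrix(0L, nr, nc)
  if (any(formed)) {
    rho <- truth_density(x_mm[formed], depth_mm[formed] / h[formed], age,
                         params)
    if (noise_frac > 0) {
      z <- with_local_seed(seed, {
        z <- rnorm(length(rho))
        pmin(pmax(z, -4), 4)
      })
      rho <- rho * (1 + noise_frac * z)
    }
    grey <- round((rho - calib$intercept) / calib$slope)
    n_clip <- sum(grey < 1 | grey > 65535)
    if (n_clip > 0) {
      warning(sprintf("%d pixel(s) outside the calibration's grey range were clipped",
                      n_clip), call. = FALSE)
    }
    pixels[formed] <- as.integer(pmin(pmax(grey, 1), 65535))
  }
  structure(
    list(specimen_id = specimen_id, age_days = age, batch = batch,
         molar = molar, worn = worn, pixels = pixels, pixel_size_mm = px,
         geometry = list(horn_row = r0, horn_col = c0, theta = theta)),
    class = "tooth_section"
  )
}

#' Default death-age structure for a synthetic ontogenetic series
#'
#' A cross-sectional series of naturally deceased animals is front-loaded
#' with young deaths (mortality concentrates in the first months of life),
#' so the default ages follow `t_max * u^1.7` on a regular grid of `u`,
#' giving a median age around 165 days over a 0-540 day span.
#'
#' @param n Number of specimens.
#' @param t_max Oldest age, days.
#' @param power Skew exponent (1 = uniform ages).
#' @return Ages in days, ascending.
#' @export
synthetic_series_ages <- function(n = 45, t_max = 540, power = 1.7) {
  t_max * seq(0, 1, length.out = n)^power
}

#' Simulate an ontogenetic series of sections
#'
#' Renders one section per age from a single shared growth model, with
#' per-specimen noise seeds derived deterministically from the master seed.
#'
#' @param params A [wave_model_params()] object.
#' @param ages Ages at death in days (non-empty).
#' @param calib Calibration used to render grey values.
#' @param pixel_size_mm Rendered pixel size, mm.
#' @param noise_frac Relative noise (defaults to the generator's value).
#' @param seed Master seed.
#' @return A list with `sections` (list of `tooth_section`), `manifest`
#'   (tibble: id, age_days, batch, molar, worn, filename) and `params`.
#' @export
simulate_series <- function(params, ages, calib = synthetic_calibration(),
                            pixel_size_mm = 0.2, noise_frac = NULL,
                            seed = params$seed) {
  stopifnot(length(ages) >= 1)
  ids <- sprintf("S%03d", seq_along(ages))
  seeds <- (as.double(seed) * 1000003 + seq_along(ages)) %% 2147483647
  sections <- purrr::map2(ages, seq_along(ages), function(a, i) {
    render_section(params, a, calib = calib, pixel_size_mm = pixel_size_mm,
                   noise_frac = noise_frac, seed = as.integer(seeds[i]),
                   specimen_id = ids[i])
  })
  manifest <- tibble::tibble(
    id = ids, age_days = ages, batch = calib$batch_id, molar = "M1",
    worn = FALSE,
    filename = sprintf("%d_%s_%s.tif", round(ages), calib$batch_id, ids)
  )
  list(sections = sections, manifest = manifest, params = params)
}

#' Write a simulated series to disk
#'
#' Sections are written as 16-bit grayscale TIFFs named
#' `<age-days>_<batch>_<id>.tif` next to a CSV manifest
#' (id, age_days, batch, molar, worn, filename).
#'
#' @param series Result of [simulate_series()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  purrr::walk2(series$sections, series$manifest$filename, function(sec, fn) {
    tiff::writeTIFF(sec$pixels / 65535, file.path(dir, fn),
                    bits.per.sample = 16L)
  })
  path <- file.path(dir, "manifest.csv")
  write.csv(series$manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write simulated ground truth to an HDF5 sidecar
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output HDF5 file path.
#' @return Invisibly, `path`.
#' @export
write_truth_h5 <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(truth$density, path, "density")
  rhdf5::h5write(truth$x_mm, path, "x_mm")
  rhdf5::h5write(truth$depth_rel, path, "depth_rel")
  rhdf5::h5write(truth$times, path, "times")
  rhdf5::h5write(truth$secretion_onset, path, "secretion_onset")
  rhdf5::h5write(truth$maturation_onset, path, "maturation_onset")
  rhdf5::h5write(truth$maturation_completion, path, "maturation_completion")
  rhdf5::h5closeAll()
  invisible(path)
}
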