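#' Assemble per-pixel posteriors into the HDF5 mineralization model
#'
#' Writes the standard four-dataset HDF5 schema: `age_mask` (specimens x
#' pixels, binary presence), `ages` (days per specimen), `locations`
#' (pixels x 2 standardized tooth coordinates) and `pct_min_samples`
#' (retained samples x pixels x specimen-ages, densities stored as percent
#' of the reference maximum). Absent pixel-ages hold the sentinel -1 with
#' `age_mask` 0 (rectangular HDF5 arrays need a fill value); file
#' attributes record the reference density, seed and sentinel.
#'
#' @param posteriors A `pixel_posteriors` object from [run_all_pixels()].
#' @param path Output HDF5 path (overwritten).
#' @param reference_density Reference maximum density, g/cm^3.
#' @return A `mineralization_model`: in-memory copies of the four datasets
#'   plus `locations_mm` metadata and `path`.
#' @export
assemble_model <- function(posteriors, path, reference_density = 2.62) {
  stopifnot(inherits(posteriors, "pixel_posteriors"))
  usable <- vapply(posteriors$posteriors, function(p) isTRUE(p$usable),
                   logical(1))
  posts <- posteriors$posteriors[usable]
  index <- posteriors$index[usable, , drop = FALSE]
  n_pix <- length(posts)
  stopifnot(n_pix >= 1)
  n_spec <- length(posteriors$times)
  n_keep <- nrow(posts[[1]]$samples)
  if (!all(vapply(posts, function(p) length(p$present) == n_spec,
                  logical(1)))) {
    stop("pixels do not share a common specimen roster", call. = FALSE)
  }

  age_mask <- matrix(0L, n_spec, n_pix)
  pct <- array(-1, c(n_keep, n_pix, n_spec))
  for (j in seq_len(n_pix)) {
    p <- posts[[j]]
    age_mask[p$present, j] <- 1L
    pct[, j, p$present] <- p$samples / reference_density * 100
  }
  ages <- posteriors$times
  locations <- cbind(index$x_bin, index$depth_bin)

  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(age_mask, path, "age_mask")
  rhdf5::h5write(ages, path, "ages")
  rhdf5::h5write(locations, path, "locations")
  rhdf5::h5write(pct, path, "pct_min_samples")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(reference_density, fid, "reference_density")
  rhdf5::h5writeAttribute(-1, fid, "absent_sentinel")
  rhdf5::h5writeAttribute(as.double(posteriors$seed), fid, "seed")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()

  structure(
    list(age_mask = age_mask, ages = ages, locations = locations,
         pct_min_samples = pct, reference_density = reference_density,
         index = index, path = path),
    class = "mineralization_model"
  )
}

#' Read a mineralization model back from HDF5
#'
#' @param path HDF5 file written by [assemble_model()].
#' @return A `mineralization_model`.
#' @export
read_model <- function(path) {
  age_mask <- rhdf5::h5read(path, "age_mask")
  ages <- as.vector(rhdf5::h5read(path, "ages"))
  locations <- rhdf5::h5read(path, "locations")
  pct <- rhdf5::h5read(path, "pct_min_samples")
  ref <- tryCatch(as.vector(rhdf5::h5readAttributes(path, "/")$reference_density),
                  error = function(e) 2.62)
  rhdf5::h5closeAll()
  structure(
    list(age_mask = age_mask, ages = ages, locations = locations,
         pct_min_samples = pct, reference_density = ref %||% 2.62,
         index = NULL, path = path),
    class = "mineralization_model"
  )
}

#' Number of density estimates in a daily-interpolated model
#'
#' Shape identity only: `n_pixels * n_days * n_keep`, computed from the
#' container's metadata without materializing the interpolated array. At
#' the published scale (12,000 pixels, 280 days, 100 retained samples)
#' this is 336 million.
#'
#' @param model A `mineralization_model`, or `NULL` if `n_pixels` is given.
#' @param n_days Days in the interpolation window.
#' @param n_pixels,n_keep Overrides; default taken from the model's shape.
#' @return The estimate count (double).
#' @export
n_density_estimates <- function(model = NULL, n_days = 280,
                                n_pixels = NULL, n_keep = NULL) {
  if (!is.null(model)) {
    d <- dim(model$pct_min_samples)
    n_keep <- n_keep %||% d[1]
    n_pixels <- n_pixels %||% d[2]
  }
  as.double(n_pixels) * as.double(n_days) * as.double(n_keep)
}

#' Interpolate retained trajectories onto a daily grid
#'
#' Linearly interpolates each pixel's retained samples from the specimen
#' age grid onto a uniform daily grid. Linear interpolation preserves
#' monotonicity, so daily trajectories remain non-decreasing. Densities
#' before the pixel's first present age are 0 (nothing deposited yet);
#' after the last present age the final sampled value is held.
#'
#' @param model A `mineralization_model`.
#' @param n_days Length of the daily window.
#' @param start_day First day of the window; default the earliest modeled
#'   age.
#' @return A `daily_trajectories`: `density_pct` (array samples x pixels x
#'   days, percent of reference), `days`, `locations`, plus pixel exclusion
#'   info.
#' @export
interpolate_daily <- function(model, n_days = 280, start_day = NULL) {
  stopifnot(inherits(model, "mineralization_model"))
  pct <- model$pct_min_samples
  n_keep <- dim(pct)[1]; n_pix <- dim(pct)[2]
  ages <- model$ages
  start_day <- start_day %||% floor(min(ages))
  days <- seq(start_day, by = 1, length.out = n_days)

  out <- array(NA_real_, c(n_keep, n_pix, n_days))
  excluded <- integer(0)
  for (j in seq_len(n_pix)) {
    present <- model$age_mask[, j] == 1
    if (sum(present) < 2) { excluded <- c(excluded, j); next }
    tp <- ages[present]
    for (k in seq_len(n_keep)) {
      y <- pct[k, j, present]
      yi <- approx(tp, y, xout = days, rule = 2)$y
      yi[days < tp[1]] <- 0
      out[k, j, ] <- yi
    }
  }
  if (length(excluded) > 0) {
    message(sprintf("interpolate_daily: excluded %d pixel(s) with < 2 present ages",
                    length(excluded)))
  }
  structure(
    list(density_pct = out, days = days, locations = model$locations,
         excluded = excluded, reference_density = model$reference_density,
         index = model$index),
    class = "daily_trajectories"
  )
}

#' Mineralization-rate field
#'
#' First difference over time of a posterior summary trajectory (mean by
#' default) per pixel: percent of mature density deposited per day.
#' Monotone trajectories guarantee non-negative rates.
#'
#' @param daily A `daily_trajectories` object.
#' @param statistic `"mean"` or `"median"` posterior summary.
#' @return A `rate_field`: `rates` (matrix pixels x days-1, % per day),
#'   `days` (midpoints), `locations`, `summary` (pixels x days summary
#'   trajectory).
#' @export
rate_field <- function(daily, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(daily, "daily_trajectories"))
  f <- if (statistic == "mean") colMeans else function(m) apply(m, 2, median)
  n_pix <- dim(daily$density_pct)[2]
  n_days <- dim(daily$density_pct)[3]
  summ <- matrix(NA_real_, n_pix, n_days)
  for (j in seq_len(n_pix)) {
    summ[j, ] <- f(daily$density_pct[, j, ])
  }
  rates <- t(apply(summ, 1, diff))
  structure(
    list(rates = rates, days = daily$days[-1] - 0.5,
         locations = daily$locations, summary = summ,
         summary_days = daily$days, index = daily$index,
         statistic = statistic),
    class = "rate_field"
  )
}

#' Per-pixel time averaging of mineralization
#'
#' For each pixel, the interval between first mineral deposition (first
#' nonzero density on the posterior-mean daily trajectory) and the
#' attainment of `end_frac` of the reference maximum. This is the window
#' over which chemical inputs are blended into that location's mineral.
#' Pixels that never reach `end_frac` are flagged incomplete (NA days).
#'
#' @param daily A `daily_trajectories` object.
#' @param end_frac Completion threshold as a fraction of the reference
#'   maximum (default 0.85, the maturation-completion landmark).
#' @return A tibble: `pixel`, `x_bin`, `depth_bin`, `onset_day`,
#'   `completion_day`, `days_averaged`, `incomplete`.
#' @export
time_averaging_map <- function(daily, end_frac = 0.85) {
  stopifnot(inherits(daily, "daily_trajectories"))
  n_pix <- dim(daily$density_pct)[2]
  days <- daily$days
  rows <- purrr::map(seq_len(n_pix), function(j) {
    m <- colMeans(matrix(daily$density_pct[, j, ],
                         nrow = dim(daily$density_pct)[1]))
    if (all(is.na(m))) return(NULL)
    nz <- which(m > 0)
    if (length(nz) == 0) return(NULL)
    onset <- days[min(nz)]
    thr <- end_frac * 100
    hit <- which(m >= thr)
    completion <- if (length(hit) == 0) NA_real_ else {
      i <- min(hit)
      if (i == 1) days[1] else {
        # linear crossing between the bracketing days
        days[i - 1] + (thr - m[i - 1]) / (m[i] - m[i - 1])
      }
    }
    tibble::tibble(
      pixel = j,
      x_bin = daily$locations[j, 1], depth_bin = daily$locations[j, 2],
      onset_day = onset, completion_day = completion,
      days_averaged = completion - onset, incomplete = is.na(completion)
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize time averaging by enamel depth band
#'
#' @param tam Output of [time_averaging_map()].
#' @param n_depth_bins Total depth bins in the standardized grid.
#' @return A tibble with mean/median days averaged for inner
#'   (EDJ-adjacent), mid, and outer thirds of the enamel.
#' @export
time_averaging_by_band <- function(tam, n_depth_bins = max(tam$depth_bin)) {
  tam |>
    dplyr::filter(!.data$incomplete) |>
    dplyr::mutate(band = cut(.data$depth_bin / n_depth_bins,
                             breaks = c(0, 1 / 3, 2 / 3, 1),
                             labels = c("inner", "mid", "outer"),
                             include.lowest = TRUE)) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(mean_days = mean(.data$days_averaged),
                     median_days = median(.data$days_averaged),
                     n = dplyr::n(), .groups = "drop")
}

# separable 1-D Gaussian filter with edge renormalization
gauss_filter_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Export Gaussian-blurred rate-field animation frames
#'
#' Maps the rate field back onto the standardized (EDJ distance x depth)
#' grid, blurs with an isotropic spatial Gaussian (sd `sigma_xy` pixels)
#' and a temporal Gaussian (sd `sigma_t` days), and writes one grayscale
#' PNG per day on a fixed color scale. `sigma = 0` disables the blur.
#'
#' @param rates A `rate_field` object.
#' @param dir Output directory.
#' @param sigma_xy Spatial blur sd, pixels.
#' @param sigma_t Temporal blur sd, days.
#' @param grid_dims `(n distance bins, n depth bins)`; default inferred
#'   from the locations.
#' @return Invisibly, a list with the blurred frame array
#'   (`[x, depth, day]`) and the written file names.
#' @export
export_animation_frames <- function(rates, dir, sigma_xy = 1, sigma_t = 8,
                                    grid_dims = NULL) {
  stopifnot(inherits(rates, "rate_field"))
  loc <- rates$locations
  grid_dims <- grid_dims %||% c(max(loc[, 1]), max(loc[, 2]))
  n_days <- ncol(rates$rates)
  frames <- array(0, c(grid_dims[1], grid_dims[2], n_days))
  for (j in seq_len(nrow(loc))) {
    frames[loc[j, 1], loc[j, 2], ] <- rates$rates[j, ]
  }
  if (sigma_xy > 0) {
    for (d in seq_len(n_days)) {
      f <- frames[, , d]
      f <- apply(f, 2, gauss_filter_1d, sigma = sigma_xy)
      f <- t(apply(f, 1, gauss_filter_1d, sigma = sigma_xy))
      frames[, , d] <- f
    }
  }
  if (sigma_t > 0) {
    for (i in seq_len(grid_dims[1])) {
      for (j in seq_len(grid_dims[2])) {
        frames[i, j, ] <- gauss_filter_1d(frames[i, j, ], sigma_t)
      }
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vmax <- max(frames, 1e-12)
  files <- character(n_days)
  for (d in seq_len(n_days)) {
    img <- pmin(pmax(frames[, , d] / vmax, 0), 1)
    files[d] <- file.path(dir, sprintf("frame_%04d.png", d))
    png::writePNG(t(img), files[d])
  }
  invisible(list(frames = frames, files = files, scale_max = vmax))
}
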