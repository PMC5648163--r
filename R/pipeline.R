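#' Run the full mineralization-modeling pipeline on a synthetic series
#'
#' Chains every stage end to end: simulate an ontogenetic series of
#' sections, calibrate grey values to densities, trace and flatten along
#' the EDJ, measure landmarks, fit the extension growth curve, re-assign
#' size-modeled ages, sample monotone mineralization trajectories per
#' standardized pixel, assemble the HDF5 model, and derive daily
#' trajectories. Mainly a convenience for simulation studies and a worked
#' example of how the stages connect for real data.
#'
#' @param params A [wave_model_params()] object.
#' @param ages Ages at death, days.
#' @param calib Calibration used for rendering and re-reading.
#' @param pixel_size_mm Rendered pixel size, mm.
#' @param noise_frac Rendering noise (defaults to the generator's value).
#' @param n_depth_bins Depth bins for flattening.
#' @param mcmc List of sampler settings overriding the defaults
#'   (`n_samples`, `n_walkers`, `n_keep`, `sigma`).
#' @param model_path Output HDF5 path (default: a tempfile).
#' @param n_days Daily-interpolation window length.
#' @param seed Master seed for rendering and sampling.
#' @param x_stride Subsample every `x_stride`-th EDJ distance bin before
#'   sampling (1 = all pixels); controls problem size in simulation
#'   studies.
#' @return A list with the intermediate products of every stage:
#'   `series`, `dmaps`, `flats`, `landmarks`, `extension_fit`, `records`,
#'   `stack`, `posteriors`, `model`, `daily`.
#' @export
run_mineralization_pipeline <- function(params = wave_model_params(),
                                        ages,
                                        calib = synthetic_calibration(),
                                        pixel_size_mm = 0.2,
                                        noise_frac = NULL,
                                        n_depth_bins = 10,
                                        mcmc = list(),
                                        model_path = tempfile(fileext = ".h5"),
                                        n_days = 280,
                                        seed = 1L,
                                        x_stride = 1L) {
  mc <- utils::modifyList(
    list(n_samples = 20000, n_walkers = 4, n_keep = 100,
         sigma = 0.05 * 2.62),
    mcmc
  )
  series <- simulate_series(params, ages, calib = calib,
                            pixel_size_mm = pixel_size_mm,
                            noise_frac = noise_frac, seed = seed)
  dmaps <- purrr::map(series$sections, calibrate_section, calib = calib)
  flats <- purrr::map(dmaps, flatten_enamel, n_depth_bins = n_depth_bins)
  landmarks <- landmark_table(flats)

  ext_fit <- fit_growth_curve(
    tibble::tibble(age_days = landmarks$age_days,
                   position_mm = landmarks$e_l_mm),
    initiation_day = truth_extension_time(0, params),
    curve_kind = "extension", seed = seed
  )
  records <- reassign_ages(
    tibble::tibble(specimen_id = landmarks$specimen_id,
                   age_days = landmarks$age_days,
                   e_l_mm = landmarks$e_l_mm),
    ext_fit
  )
  # keep flats aligned with the reordered records
  flats_by_id <- setNames(flats, landmarks$specimen_id)
  stack <- build_pixel_stack(flats_by_id[records$specimen_id], records)
  if (x_stride > 1L) {
    keep <- seq(1, dim(stack$densities)[2], by = x_stride)
    stack$densities <- stack$densities[, keep, , drop = FALSE]
    stack$x_mm <- stack$x_mm[keep]
  }
  posteriors <- run_all_pixels(stack, n_samples = mc$n_samples,
                               n_walkers = mc$n_walkers,
                               n_keep = mc$n_keep, seed = seed,
                               sigma = mc$sigma)
  model <- assemble_model(posteriors, model_path,
                          reference_density = params$max_density)
  daily <- interpolate_daily(model, n_days = n_days)
  list(series = series, dmaps = dmaps, flats = flats,
       landmarks = landmarks, extension_fit = ext_fit, records = records,
       stack = stack, posteriors = posteriors, model = model, daily = daily)
}
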