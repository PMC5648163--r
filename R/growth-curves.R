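#' Integrated-Gaussian growth-curve parameters
#'
#' Crown extension (and the progress of maturation onset/completion along
#' the EDJ) is modeled as a sigmoid error function of age,
#' `el(t) = el_max - a + a * erf(s*t - o*s)`, with amplitude `a` (mm), slope
#' `s` (1/day), offset `o` (days) and mature maximum length `el_max` (mm).
#' A Gaussian rate profile is used because extension rates peak shortly
#' after crown initiation and decline thereafter.
#'
#' @param a Amplitude, mm (> 0).
#' @param s Slope, 1/day (> 0).
#' @param o Offset, days.
#' @param el_max Mature maximum length, mm (> 0).
#' @param curve_kind One of `"extension"`, `"onset"`, `"completion"`.
#' @return An object of class `growth_curve_params`.
#' @export
growth_curve_params <- function(a, s, o, el_max,
                                curve_kind = c("extension", "onset",
                                               "completion")) {
  stopifnot(a > 0, s > 0, el_max > 0)
  structure(list(a = a, s = s, o = o, el_max = el_max,
                 curve_kind = match.arg(curve_kind)),
            class = "growth_curve_params")
}

#' Forward growth curve: position along the EDJ at a given age
#'
#' @param t Ages, days.
#' @param p A [growth_curve_params()] object.
#' @return Positions `el_max - a + a * erf(s*(t - o))`, mm; non-decreasing
#'   in `t` and bounded above by `el_max`.
#' @export
extension_length <- function(t, p) {
  p$el_max - p$a + p$a * erf(p$s * t - p$o * p$s)
}

#' Size-modeled age from extension length (inverse growth curve)
#'
#' Inverts the error-function growth curve to re-assign a modeled age
#' `t_m = [erfinv((a + e_l - el_max)/a) + o*s] / s` to a specimen from its
#' extension length. Cross-sectional series mix individual growth variation
#' with age; the size-modeled age places each specimen on the population
#' curve.
#'
#' @param e_l Extension lengths, mm.
#' @param p A [growth_curve_params()] object.
#' @return Modeled ages in days; strictly increasing in `e_l`.
#' @export
extension_age <- function(e_l, p) {
  z <- (p$a + e_l - p$el_max) / p$a
  if (any(z <= -1 | z >= 1)) {
    stop("extension length outside the invertible range (el_max - 2a, el_max)",
         call. = FALSE)
  }
  (erfinv(z) + p$o * p$s) / p$s
}

# profile least squares: given (s, o) and fixed el_max, the model
# position = el_max - a * (1 - erf(s*(t - o))) is linear in a
profile_rss <- function(s, o, t, pos, el_max, initiation_day, eps_init,
                        penalty = 1e6) {
  z <- 1 - erf(s * (t - o))
  sz2 <- sum(z^2)
  a <- if (sz2 < 1e-12) NA_real_ else sum(z * (el_max - pos)) / sz2
  if (!is.finite(a) || a <= 0) return(list(rss = Inf, a = NA_real_))
  resid <- pos - (el_max - a * z)
  rss <- sum(resid^2)
  # crown length at initiation must be physical: 0 <= el(init) <= eps_init
  el_init <- el_max - a * (1 - erf(s * (initiation_day - o)))
  viol <- max(0, el_init - eps_init) + max(0, -el_init)
  list(rss = rss + penalty * viol^2, a = a, raw_rss = rss, viol = viol)
}

#' Fit an error-function growth curve to landmark positions
#'
#' Least-squares fit of `(a, s, o)` in position space (residuals are
#' `position - extension_length(age)`, in mm), subject to a hard initiation
#' constraint `extension_length(initiation_day) <= eps_init` (the crown has
#' essentially zero length at initiation; -49 days for first molars, +84
#' for second molars). The search runs a global stage (Latin-hypercube
#' multistart over a bounded `(s, o)` box, with the amplitude profiled out
#' in closed form) followed by derivative-free local refinement, echoing
#' the usual global-then-local treatment of this non-convex fit.
#'
#' @param data A data frame with columns `age_days` and `position_mm` (>= 3
#'   rows spanning a nontrivial age range).
#' @param el_max Mature maximum length, mm; defaults to the largest
#'   observed position.
#' @param initiation_day Crown initiation age, days (default -49, first
#'   molar).
#' @param curve_kind Which landmark the positions describe.
#' @param eps_init Initiation constraint tolerance, mm (default 0.25,
#'   roughly a pixel).
#' @param n_starts Number of multistart samples in the global stage.
#' @param seed Seed for the multistart sample.
#' @return An object of class `growth_curve_fit`: the fitted
#'   [growth_curve_params()], residual tibble, RSS and fit metadata.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_growth_curve <- function(data, el_max = NULL, initiation_day = -49,
                             curve_kind = c("extension", "onset",
                                            "completion"),
                             eps_init = 0.25, n_starts = 200, seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  t <- data$age_days
  pos <- data$position_mm
  ok <- is.finite(t) & is.finite(pos)
  t <- t[ok]; pos <- pos[ok]
  if (length(t) < 3 || diff(range(t)) <= 0) {
    stop("need at least 3 landmark points spanning a nontrivial age range",
         call. = FALSE)
  }
  el_max <- el_max %||% max(pos)
  t_span <- diff(range(t))

  # bounded (log10 s, o) box for the global stage
  lo <- c(log10(0.2 / t_span), initiation_day)
  hi <- c(log10(50 / t_span), max(t))
  starts <- with_local_seed(seed, lhs::randomLHS(n_starts, 2))
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")

  obj <- function(par) {
    s <- 10^par[1]; o <- par[2]
    profile_rss(s, o, t, pos, el_max, initiation_day, eps_init)$rss
  }
  vals <- apply(starts, 1, obj)
  top <- order(vals)[seq_len(min(5, n_starts))]

  best <- NULL
  for (i in top) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  s <- 10^best$par[1]; o <- best$par[2]
  prof <- profile_rss(s, o, t, pos, el_max, initiation_day, eps_init)
  if (!is.finite(prof$rss) || prof$viol > 1e-3) {
    stop(sprintf(paste0("growth-curve fit failed to satisfy the initiation ",
                        "constraint: el(%g) exceeds %g mm by %.3g mm"),
                 initiation_day, eps_init, prof$viol), call. = FALSE)
  }
  params <- growth_curve_params(prof$a, s, o, el_max, curve_kind)
  fitted <- extension_length(t, params)
  structure(
    list(params = params,
         residuals = tibble::tibble(age_days = t, position_mm = pos,
                                    fitted_mm = fitted,
                                    residual_mm = pos - fitted),
         rss = prof$raw_rss, n = length(t), el_max = el_max,
         initiation_day = initiation_day, eps_init = eps_init,
         seed = seed, curve_kind = curve_kind),
    class = "growth_curve_fit"
  )
}

#' @export
print.growth_curve_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Error-function growth curve (%s), n = %d\n", x$curve_kind, x$n))
  cat(sprintf("  a = %.4g mm, s = %.4g /day, o = %.4g days, el_max = %.4g mm\n",
              p$a, p$s, p$o, p$el_max))
  cat(sprintf("  RSS = %.4g mm^2; initiation el(%g d) = %.3g mm\n",
              x$rss, x$initiation_day,
              extension_length(x$initiation_day, p)))
  invisible(x)
}

#' @rdname fit_growth_curve
#' @param x A `growth_curve_fit`.
#' @param ... Unused.
#' @export
tidy.growth_curve_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("a", "s", "o", "el_max"),
    estimate = c(p$a, p$s, p$o, p$el_max),
    unit = c("mm", "1/day", "days", "mm")
  )
}

#' @rdname fit_growth_curve
#' @export
glance.growth_curve_fit <- function(x, ...) {
  tibble::tibble(curve_kind = x$curve_kind, rss = x$rss, n = x$n,
                 df.residual = x$n - 3L,
                 sigma = sqrt(x$rss / max(1, x$n - 3L)),
                 initiation_day = x$initiation_day)
}

#' Fit extension, maturation-onset and maturation-completion curves
#'
#' @param landmarks A landmark tibble (one row per specimen) with columns
#'   `age_days`, `e_l_mm`, `onset_mm`, `completion_mm`.
#' @param el_max Shared mature maximum length; defaults to max `e_l_mm`.
#' @inheritParams fit_growth_curve
#' @return Named list of three `growth_curve_fit` objects
#'   (`extension`, `onset`, `completion`).
#' @export
fit_growth_curves <- function(landmarks, el_max = NULL, initiation_day = -49,
                              eps_init = 0.25, n_starts = 200, seed = 1L) {
  el_max <- el_max %||% max(landmarks$e_l_mm)
  cols <- c(extension = "e_l_mm", onset = "onset_mm",
            completion = "completion_mm")
  purrr::imap(cols, function(col, kind) {
    fit_growth_curve(
      tibble::tibble(age_days = landmarks$age_days,
                     position_mm = landmarks[[col]]),
      el_max = el_max, initiation_day = initiation_day, curve_kind = kind,
      eps_init = eps_init, n_starts = n_starts, seed = seed
    )
  })
}

#' Re-assign size-modeled ages to specimens
#'
#' Replaces each specimen's chronological age with the age at which the
#' fitted extension curve attains its extension length. Specimens whose
#' length is at (or numerically indistinguishable from) `el_max` keep their
#' chronological age: size carries no information once growth has ceased.
#'
#' @param records A data frame with columns `specimen_id`, `age_days`, and
#'   `e_l_mm`.
#' @param fit A `growth_curve_fit` for the extension curve.
#' @param eps_mature Relative tolerance on the erf argument beyond which a
#'   specimen is treated as fully grown.
#' @return The input tibble with a `t_m` column (size-modeled age, days),
#'   sorted by `t_m`.
#' @export
reassign_ages <- function(records, fit, eps_mature = 1e-9) {
  p <- fit$params
  records <- tibble::as_tibble(records)
  z <- (p$a + records$e_l_mm - p$el_max) / p$a
  t_m <- ifelse(z >= 1 - eps_mature,
                records$age_days,
                (erfinv(pmax(z, -1 + eps_mature)) + p$o * p$s) / p$s)
  records$t_m <- t_m
  dplyr::arrange(records, .data$t_m)
}
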