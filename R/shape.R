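#' Trace the enamel-dentin junction on a density map
#'
#' Extracts the dentin-facing boundary of the enamel mask as an ordered
#' path from the dentin horn (cuspal end) to the cervical end, with
#' cumulative arc length in mm. The mask's principal axis defines the
#' along-tooth direction; within 1-pixel bins along that axis the
#' boundary pixel on the dentin side is taken, and the resulting staircase
#' is smoothed with a short moving average so arc length is not inflated
#' by pixelation.
#'
#' @param dmap A `density_map`.
#' @param horn_hint Optional `(row, col)` near the dentin horn; the path end
#'   nearest this point becomes the origin. Default: the end with the
#'   smaller column index.
#' @param edj_side Which side of the enamel band faces dentin:
#'   `"high_row"` (default; dentin below the enamel in image coordinates)
#'   or `"low_row"`.
#' @return An `edj_path`: tibble with columns `row`, `col` (possibly
#'   fractional after smoothing) and `arc_mm` (strictly increasing).
#' @export
trace_edj <- function(dmap, horn_hint = NULL,
                      edj_side = c("high_row", "low_row")) {
  stopifnot(inherits(dmap, "density_map"))
  edj_side <- match.arg(edj_side)
  mask <- dmap$mask
  if (!any(mask)) stop("enamel mask is empty", call. = FALSE)

  lab <- label_components8(mask)
  n_comp <- max(lab)
  if (n_comp > 1) {
    sizes <- tabulate(lab[lab > 0])
    # sub-pixel debris at the thin secretory front (or speckle) is not a
    # genuine disconnection; trace the main component and ignore it
    speckle <- max(5, 0.002 * sum(sizes))
    big <- which(sizes >= speckle)
    if (length(big) > 1) {
      stop(sprintf("enamel mask is disconnected: %d components (sizes %s)",
                   n_comp, paste(sizes, collapse = ", ")), call. = FALSE)
    }
    message(sprintf("trace_edj: ignoring %d speckle component(s) (%d px)",
                    n_comp - 1L, sum(sizes[-big])))
    mask <- lab == big
  }

  idx <- which(mask, arr.ind = TRUE)
  coords <- cbind(idx[, "row"], idx[, "col"])
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  pc <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  u <- pc[, 1]
  if (u[2] < 0) u <- -u                      # along increasing column
  v <- c(-u[2], u[1])
  if (v[1] < 0) v <- -v                      # positive v towards larger rows

  pu <- cc %*% u
  pv <- cc %*% v
  bins <- round(pu - min(pu)) + 1L
  pick <- if (edj_side == "high_row") {
    tapply(seq_along(pv), bins, function(i) i[which.max(pv[i])])
  } else {
    tapply(seq_along(pv), bins, function(i) i[which.min(pv[i])])
  }
  pick <- unlist(pick[order(as.integer(names(pick)))], use.names = FALSE)
  path <- coords[pick, , drop = FALSE]
  path <- path[order(pu[pick]), , drop = FALSE]

  # moving-average smoothing of the staircase (window ~9 px, shrunk at ends)
  smooth_ma <- function(x, w = 9L) {
    n <- length(x)
    if (n < 3) return(x)
    half <- w %/% 2
    cs <- cumsum(c(0, x))
    i <- seq_len(n)
    lo <- pmax(1L, i - half); hi <- pmin(n, i + half)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  rows <- smooth_ma(path[, 1])
  cols <- smooth_ma(path[, 2])
  # pin the endpoints: edge-shrunk smoothing windows pull them inward
  n_pts <- length(rows)
  rows[c(1, n_pts)] <- path[c(1, n_pts), 1]
  cols[c(1, n_pts)] <- path[c(1, n_pts), 2]

  if (is.null(horn_hint)) horn_hint <- c(1, 1)
  d_start <- sum((c(rows[1], cols[1]) - horn_hint)^2)
  d_end <- sum((c(rows[length(rows)], cols[length(cols)]) - horn_hint)^2)
  if (d_end < d_start) {
    rows <- rev(rows); cols <- rev(cols)
  }
  seg <- sqrt(diff(rows)^2 + diff(cols)^2)
  arc <- c(0, cumsum(seg)) * dmap$pixel_size_mm
  structure(
    tibble::tibble(row = rows, col = cols, arc_mm = arc),
    class = c("edj_path", class(tibble::tibble())),
    pixel_size_mm = dmap$pixel_size_mm
  )
}

# 8-connected component labelling: 4-connected labels from EBImage merged
# across diagonal adjacencies via union-find
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  ii <- seq_len(nr - 1); jj <- seq_len(nc - 1)
  pairs <- list(
    list(a = lab[ii, jj], b = lab[ii + 1, jj + 1]),   # down-right diagonal
    list(a = lab[ii + 1, jj], b = lab[ii, jj + 1])    # up-right diagonal
  )
  for (pr in pairs) {
    touch <- pr$a > 0 & pr$b > 0 & pr$a != pr$b
    for (k in which(touch)) {
      ra <- find(pr$a[k]); rb <- find(pr$b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# mask-aware bilinear interpolation of a matrix at fractional (row, col)
bilinear_masked <- function(mat, mask, r, c) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(r); c0 <- floor(c)
  out <- numeric(length(r))
  for (k in seq_along(r)) {
    rs <- c(r0[k], r0[k] + 1); cs <- c(c0[k], c0[k] + 1)
    wr <- c(1 - (r[k] - r0[k]), r[k] - r0[k])
    wc <- c(1 - (c[k] - c0[k]), c[k] - c0[k])
    num <- 0; den <- 0
    for (i in 1:2) for (j in 1:2) {
      ri <- rs[i]; cj <- cs[j]
      if (ri >= 1 && ri <= nr && cj >= 1 && cj <= nc &&
          isTRUE(mask[ri, cj])) {
        w <- wr[i] * wc[j]
        num <- num + w * mat[ri, cj]
        den <- den + w
      }
    }
    out[k] <- if (den > 1e-9) num / den else NA_real_
  }
  out
}

#' Flatten a density map into standardized tooth coordinates
#'
#' Resamples densities along local normals to the traced EDJ, producing a
#' grid indexed by (EDJ distance bin, relative depth bin) with depth 0 at
#' the EDJ and depth 1 at the current outer enamel surface. Distance bins
#' are one pixel of arc length; depth is resampled by mask-aware bilinear
#' interpolation at bin centers.
#'
#' @param dmap A `density_map`.
#' @param edj An `edj_path` traced on this map (default: traced here).
#' @param n_depth_bins Number of relative-depth bins.
#' @return A `flattened_enamel`: list with `densities` (matrix
#'   `[distance bin, depth bin]`), `mask`, `arc_mm` (bin arc lengths),
#'   `depth_rel` (bin centers), `edj_bin_mm`, `specimen_id`, `age_days`.
#' @export
flatten_enamel <- function(dmap, edj = trace_edj(dmap), n_depth_bins = 20) {
  stopifnot(inherits(dmap, "density_map"))
  rows <- edj$row; cols <- edj$col
  n <- length(rows)
  px <- dmap$pixel_size_mm
  depth_centers <- (seq_len(n_depth_bins) - 0.5) / n_depth_bins

  # local tangents (central differences over +/-3 points)
  w <- 3L
  i_lo <- pmax(1L, seq_len(n) - w)
  i_hi <- pmin(n, seq_len(n) + w)
  tr <- rows[i_hi] - rows[i_lo]
  tc <- cols[i_hi] - cols[i_lo]
  nrm <- sqrt(tr^2 + tc^2)
  tr <- tr / nrm; tc <- tc / nrm
  # normal candidates (rotate tangent by 90 degrees)
  n_r <- -tc; n_c <- tr
  # orient normals into the enamel: majority vote over probe points
  probe <- seq(1, n, length.out = min(25, n))
  votes <- vapply(probe, function(i) {
    i <- round(i)
    p1 <- c(rows[i] + 2 * n_r[i], cols[i] + 2 * n_c[i])
    r1 <- round(p1[1]); c1 <- round(p1[2])
    inside <- r1 >= 1 && r1 <= nrow(dmap$mask) && c1 >= 1 &&
      c1 <= ncol(dmap$mask) && dmap$mask[r1, c1]
    if (inside) 1 else -1
  }, numeric(1))
  if (sum(votes) < 0) { n_r <- -n_r; n_c <- -n_c }

  dens <- matrix(NA_real_, n, n_depth_bins)
  thick_mm <- rep(NA_real_, n)
  n_failed <- 0L
  step <- 0.25
  max_steps <- ceiling((nrow(dmap$mask) + ncol(dmap$mask)) / step)
  for (i in seq_len(n)) {
    # march outward to find the current enamel surface
    k <- 0L
    repeat {
      k <- k + 1L
      r <- rows[i] + k * step * n_r[i]
      c <- cols[i] + k * step * n_c[i]
      ri <- round(r); ci <- round(c)
      inside <- ri >= 1 && ri <= nrow(dmap$mask) && ci >= 1 &&
        ci <= ncol(dmap$mask) && dmap$mask[ri, ci]
      if (!inside || k > max_steps) break
    }
    thick <- (k - 1L) * step
    if (thick < 0.3) { n_failed <- n_failed + 1L; next }
    thick_mm[i] <- thick * px
    rr <- rows[i] + depth_centers * thick * n_r[i]
    cc <- cols[i] + depth_centers * thick * n_c[i]
    dens[i, ] <- bilinear_masked(dmap$densities, dmap$mask, rr, cc)
  }
  if (n_failed > 0) {
    message(sprintf("flatten_enamel: %d EDJ bin(s) without resolvable enamel were masked",
                    n_failed))
  }
  structure(
    list(densities = dens, mask = !is.na(dens), arc_mm = edj$arc_mm,
         depth_rel = depth_centers, edj_bin_mm = px,
         n_depth_bins = n_depth_bins, thickness_mm = thick_mm,
         specimen_id = dmap$specimen_id, age_days = dmap$age_days),
    class = "flattened_enamel"
  )
}

# mid-depth (relative depth 0.5) density profile, 3-bin median filtered
mid_depth_profile <- function(flat, filter = TRUE) {
  d <- flat$depth_rel
  j <- findInterval(0.5, d)
  prof <- if (j < 1) {
    flat$densities[, 1]
  } else if (j >= length(d)) {
    flat$densities[, length(d)]
  } else {
    w <- (0.5 - d[j]) / (d[j + 1] - d[j])
    (1 - w) * flat$densities[, j] + w * flat$densities[, j + 1]
  }
  if (filter && sum(is.finite(prof)) >= 3) {
    ok <- is.finite(prof)
    prof[ok] <- runmed(prof[ok], 3)
  }
  prof
}

#' Measure growth landmarks on a flattened section
#'
#' Extension length is the arc length of the farthest masked-in distance
#' bin; maturation onset and completion positions are the farthest bins
#' whose mid-depth (relative depth 0.5) density reaches 40% and 85% of the
#' reference maximum density, after a 3-bin median filter on the mid-depth
#' profile. Positions are 0 when no bin qualifies.
#'
#' @param flat A `flattened_enamel`.
#' @param onset_frac,completion_frac Density fractions defining maturation
#'   onset and completion.
#' @param reference_density Reference maximum density, g/cm^3.
#' @param horn_offset Arc length lost to wear (added to all positions), mm.
#' @return A one-row tibble: `specimen_id`, `age_days`, `e_l_mm`,
#'   `onset_mm`, `completion_mm`, `horn_offset_mm`.
#' @export
measure_landmarks <- function(flat, onset_frac = 0.40,
                              completion_frac = 0.85,
                              reference_density = 2.62,
                              horn_offset = 0) {
  stopifnot(inherits(flat, "flattened_enamel"))
  valid <- rowSums(flat$mask) > 0
  if (!any(valid)) {
    return(tibble::tibble(specimen_id = flat$specimen_id,
                          age_days = flat$age_days, e_l_mm = 0,
                          onset_mm = 0, completion_mm = 0,
                          horn_offset_mm = horn_offset))
  }
  prof <- mid_depth_profile(flat)
  arc <- flat$arc_mm
  e_l <- max(arc[valid])
  pos_at <- function(frac) {
    hit <- which(valid & is.finite(prof) & prof >= frac * reference_density)
    if (length(hit) == 0) 0 else max(arc[hit])
  }
  tibble::tibble(
    specimen_id = flat$specimen_id, age_days = flat$age_days,
    e_l_mm = e_l + horn_offset,
    onset_mm = ifelse(pos_at(onset_frac) > 0,
                      pos_at(onset_frac) + horn_offset, 0),
    completion_mm = ifelse(pos_at(completion_frac) > 0,
                           pos_at(completion_frac) + horn_offset, 0),
    horn_offset_mm = horn_offset
  )
}

#' Landmark table for a series of flattened sections
#'
#' @param flats List of `flattened_enamel` objects.
#' @param ... Passed to [measure_landmarks()].
#' @return A tibble with one row per specimen.
#' @export
landmark_table <- function(flats, ...) {
  purrr::map_dfr(flats, measure_landmarks, ...)
}

#' Estimate cuspal arc length lost to wear
#'
#' Worn molars have lost enamel at the cusp, so their EDJ arc origin
#' underestimates true positions. The offset is estimated by sliding the
#' worn specimen's mid-depth density profile along that of the unworn
#' reference closest in apparent developmental stage and taking the
#' least-squares-optimal shift.
#'
#' @param worn A `flattened_enamel` for the worn specimen.
#' @param references List of unworn `flattened_enamel` objects; at least
#'   one must be at least as long as the worn specimen.
#' @return Offset in mm (>= 0).
#' @export
estimate_horn_offset <- function(worn, references) {
  stopifnot(inherits(worn, "flattened_enamel"))
  if (inherits(references, "flattened_enamel")) references <- list(references)
  lw <- max(worn$arc_mm[rowSums(worn$mask) > 0])
  ref_len <- vapply(references, function(r) {
    v <- rowSums(r$mask) > 0
    if (any(v)) max(r$arc_mm[v]) else 0
  }, numeric(1))
  ok <- ref_len >= lw - 1e-9
  if (!any(ok)) {
    stop("no unworn reference is at least as long as the worn specimen",
         call. = FALSE)
  }
  ref <- references[[which(ok)[which.min(ref_len[ok] - lw)]]]
  lr <- ref_len[which(ok)[which.min(ref_len[ok] - lw)]]

  pw <- mid_depth_profile(worn)
  pr <- mid_depth_profile(ref)
  ok_w <- is.finite(pw)
  aw <- worn$arc_mm[ok_w]; pw <- pw[ok_w]
  ok_r <- is.finite(pr)
  ar <- ref$arc_mm[ok_r]; pr <- pr[ok_r]

  offsets <- seq(0, max(lr - lw, 0), by = worn$edj_bin_mm)
  sse <- vapply(offsets, function(k) {
    ref_interp <- approx(ar, pr, xout = aw + k, rule = 1)$y
    keep <- is.finite(ref_interp)
    if (sum(keep) < 3) return(Inf)
    sum((pw[keep] - ref_interp[keep])^2) / sum(keep)
  }, numeric(1))
  offsets[which.min(sse)]
}
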