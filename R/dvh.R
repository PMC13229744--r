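# Voxel-based cumulative DVH per structure, DVH-derived clinical metrics,
# and the conventional plan-quality indices (Paddick CI, GI, R50).

#' Boolean structure mask on the dose grid
#'
#' Voxel centres on each dose slice are tested against the structure's
#' contour polygons with even-odd parity (so nested contours carve
#' holes); a point on a contour edge counts as inside. Contour planes are
#' matched to the nearest dose slice within half the slice spacing.
#'
#' @param dose_grid a [dose_grid()].
#' @param roi an `roi` object (see [load_structures()]).
#' @return logical 3D array congruent with the dose grid (empty, with a
#'   warning, when no contour plane overlaps the grid).
#' @export
structure_mask <- function(dose_grid, roi) {
  d <- dim(dose_grid$values)
  mask <- array(FALSE, dim = d)
  if (length(roi$contours) == 0L) {
    warning("ROI '", roi$name, "' has no contours")
    return(mask)
  }
  zs <- dose_grid$origin[3] + dose_grid$slice_offsets
  dz <- dose_grid$spacing[3]
  xc <- dose_grid$origin[1] + (seq_len(d[1]) - 1) * dose_grid$spacing[1]
  yc <- dose_grid$origin[2] + (seq_len(d[2]) - 1) * dose_grid$spacing[2]
  pts <- cbind(rep(xc, times = d[2]), rep(yc, each = d[1]))

  plane_z <- vapply(roi$contours, function(ct) ct$z, numeric(1))
  slice_of <- vapply(plane_z, function(z) {
    k <- which.min(abs(zs - z))
    if (abs(zs[k] - z) <= dz / 2 + 1e-9) k else NA_integer_
  }, integer(1))
  if (all(is.na(slice_of))) {
    warning("ROI '", roi$name, "': no contour plane overlaps the dose grid")
    return(mask)
  }
  for (k in unique(stats::na.omit(slice_of))) {
    polys <- lapply(roi$contours[which(slice_of == k)], function(ct) ct$xy)
    inside <- .points_in_polygons(pts, polys, 1e-9)
    mask[, , k] <- mask[, , k] | matrix(inside, nrow = d[1])
  }
  mask
}

#' Cumulative dose-volume histogram of a structure
#'
#' Dose values at voxel centres inside the structure are binned at 1 cGy
#' resolution; the differential histogram is converted to cumulative
#' form (volume receiving at least each bin dose).
#'
#' @param dose_grid a [dose_grid()].
#' @param roi an `roi` object or a precomputed logical mask.
#' @return a `dvh` object: `list(dose_gy =, volume_mm3 =, volume_pct =,
#'   structure =, total_mm3 =)` with `dose_gy` the bin edges at 1 cGy
#'   pitch and the volumes non-increasing.
#' @export
compute_dvh <- function(dose_grid, roi) {
  name <- if (inherits(roi, "roi")) roi$name else "structure"
  mask <- if (inherits(roi, "roi")) structure_mask(dose_grid, roi) else roi
  nvox <- sum(mask)
  if (nvox == 0L) stop("structure '", name, "' has an empty mask")
  doses_cgy <- dose_grid$values[mask] * 100
  voxvol <- prod(dose_grid$spacing)
  m <- ceiling(max(doses_cgy)) + 1L
  # counts[k] = voxels with dose in [k-1, k) cGy
  counts <- tabulate(pmin(floor(doses_cgy), m - 1L) + 1L, nbins = m)
  cum <- c(nvox, nvox - cumsum(counts)) * voxvol
  structure(list(dose_gy = (0:m) / 100, volume_mm3 = cum,
                 volume_pct = 100 * cum / (nvox * voxvol),
                 structure = name, total_mm3 = nvox * voxvol),
            class = "dvh")
}

#' Dose covering x percent of the structure (Dx)
#'
#' Linear interpolation on the cumulative DVH between the bins bracketing
#' the requested volume fraction. Requests beyond the curve's support
#' clamp to the curve end and carry `attr(, "clamped") = TRUE`.
#'
#' @param dvh a [compute_dvh()] result.
#' @param x_percent volume fraction in percent, 0 < x <= 100.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, x_percent) {
  stopifnot(x_percent > 0, x_percent <= 100)
  p <- dvh$volume_pct
  d <- dvh$dose_gy
  if (x_percent > p[1]) return(structure(d[1], clamped = TRUE))
  k <- which(p < x_percent)
  if (length(k) == 0L) return(structure(d[length(d)], clamped = TRUE))
  k <- k[1]
  # interpolate between (d[k-1], p[k-1]) and (d[k], p[k])
  structure(d[k - 1] + (d[k] - d[k - 1]) *
              (p[k - 1] - x_percent) / (p[k - 1] - p[k]),
            clamped = FALSE)
}

#' Volume receiving at least x Gy (Vx)
#'
#' Interpolated cumulative volume at the requested dose.
#'
#' @inheritParams dose_at_volume
#' @param x_gy dose in Gy (non-negative).
#' @return `list(pct =, mm3 =)`.
#' @export
volume_at_dose <- function(dvh, x_gy) {
  stopifnot(x_gy >= 0)
  last <- length(dvh$dose_gy)
  pct <- if (x_gy >= dvh$dose_gy[last]) 0 else {
    stats::approx(dvh$dose_gy, dvh$volume_pct, xout = x_gy)$y
  }
  list(pct = pct, mm3 = pct / 100 * dvh$total_mm3)
}

#' DVH summary statistics
#'
#' Mean dose by trapezoidal integration of the normalised cumulative
#' curve over dose; maximum and minimum as the D2 and D98 surrogates.
#'
#' @inheritParams dose_at_volume
#' @return `list(mean_gy =, max_gy =, min_gy =)`.
#' @export
dvh_summary <- function(dvh) {
  f <- dvh$volume_pct / 100
  d <- dvh$dose_gy
  mean_gy <- sum(diff(d) * (f[-1] + f[-length(f)]) / 2)
  list(mean_gy = mean_gy,
       max_gy = as.numeric(dose_at_volume(dvh, 2)),
       min_gy = as.numeric(dose_at_volume(dvh, 98)))
}

#' Paddick conformity index
#'
#' `CI = (TV intersect PIV)^2 / (TV * PIV)`; 1 means perfect conformity.
#'
#' @param tv_mask,piv_mask logical 3D arrays on the same grid (target
#'   volume and prescription isodose volume); both must be non-empty.
#' @param spacing voxel spacing in mm.
#' @return conformity index in `[0, 1]`.
#' @export
paddick_ci <- function(tv_mask, piv_mask, spacing) {
  tv <- sum(tv_mask)
  piv <- sum(piv_mask)
  if (tv == 0L || piv == 0L) stop("empty target or prescription isodose mask")
  ov <- sum(tv_mask & piv_mask)
  (as.numeric(ov)^2) / (as.numeric(tv) * as.numeric(piv))
}

#' Gradient index
#'
#' `GI = V(50% Rx) / V(Rx)`: the ratio of the half-prescription isodose
#' volume to the prescription isodose volume.
#'
#' @param dose_grid a [dose_grid()].
#' @param rx_gy prescription dose in Gy (must not exceed the maximum dose).
#' @return gradient index (>= 1 for nested isodose volumes).
#' @export
gradient_index <- function(dose_grid, rx_gy) {
  stopifnot(rx_gy <= max(dose_grid$values))
  v_rx <- sum(dose_grid$values >= rx_gy)
  if (v_rx == 0L) stop("empty prescription isodose volume")
  sum(dose_grid$values >= 0.5 * rx_gy) / v_rx
}

#' R50: half-prescription isodose volume over target volume
#'
#' @inheritParams gradient_index
#' @param tv_volume target volume in mm^3 (positive).
#' @return the R50 ratio.
#' @export
r50 <- function(dose_grid, rx_gy, tv_volume) {
  stopifnot(tv_volume > 0)
  v50 <- sum(dose_grid$values >= 0.5 * rx_gy) * prod(dose_grid$spacing)
  v50 / tv_volume
}
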