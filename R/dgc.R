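# Dose gradient curve: symmetric dose-level generation around the
# prescription, differential and cumulative dose gradient indices, and
# clinical quality grading.
#
# The differential index for the shell between adjacent isodose surfaces
# at d and d + delta is
#
#     dDGI_d = [V(d) - V(d + delta)] / (0.5 * [S(d) + S(d + delta)])
#
# i.e. shell volume over mean shell surface area -- the average physical
# distance (mm) between the two surfaces. The cumulative index at level i
# sums the shell distances from i up to the reference dose D0, with
# cDGI_{D0} = 0 by definition.

#' Generate isodose calculation levels
#'
#' Levels are placed symmetrically around the prescription dose at
#' multiples of the step, clipped to `[low_frac * rx_gy, dmax_gy]`, so the
#' prescription itself is always an explicit level. Percentage steps are
#' converted as `delta = step/100 * rx_gy`.
#'
#' @param rx_gy prescription (reference) dose in Gy.
#' @param step step size, in Gy or percent of the prescription.
#' @param step_unit `"percent"` (default) or `"Gy"`.
#' @param low_frac lower bound as a fraction of the prescription
#'   (default 0.3).
#' @param dmax_gy upper clip, normally the maximum dose of the grid.
#' @return increasing numeric vector of dose levels (Gy) with the step in
#'   attribute `"delta_d"`.
#' @export
generate_dose_levels <- function(rx_gy, step = 1,
                                 step_unit = c("percent", "Gy"),
                                 low_frac = 0.3, dmax_gy) {
  step_unit <- match.arg(step_unit)
  stopifnot(rx_gy > 0, step > 0, low_frac > 0, low_frac < 1)
  delta <- if (step_unit == "percent") step / 100 * rx_gy else step
  lo <- low_frac * rx_gy
  ks <- seq.int(ceiling((lo - rx_gy) / delta - 1e-9),
                floor((dmax_gy - rx_gy) / delta + 1e-9))
  levels <- rx_gy + ks * delta
  levels <- levels[levels >= lo - 1e-9 & levels <= dmax_gy + 1e-9]
  if (length(levels) < 2L) {
    stop("step ", step, " ", step_unit, " leaves fewer than 2 dose levels ",
         "between ", signif(lo, 4), " and ", signif(dmax_gy, 4), " Gy")
  }
  structure(levels, delta_d = delta)
}

#' Differential dose gradient index of one shell
#'
#' `(v_d - v_next) / (0.5 * (s_d + s_next))`: the average distance in mm
#' between the isodose surface at `d` and the one at `d + delta`, when
#' volumes are in mm^3 and areas in mm^2.
#'
#' @param v_d,v_next enclosed volumes (mm^3) at `d` and `d + delta`;
#'   nesting requires `v_d >= v_next`.
#' @param s_d,s_next surface areas (mm^2) at the two levels.
#' @return shell distance in mm; `NaN` with a warning when the mean
#'   surface area is zero (undefined shell).
#' @export
ddgi <- function(v_d, v_next, s_d, s_next) {
  if (v_d < v_next) stop("isodose volumes are not nested (v_d < v_next)")
  s_mean <- (s_d + s_next) / 2
  if (s_mean <= 0) {
    warning("zero mean surface area: dDGI undefined for this shell")
    return(NaN)
  }
  (v_d - v_next) / s_mean
}

#' Normalise a dDGI value by the dose step
#'
#' Raw dDGI scales proportionally with the step size; dividing by
#' `delta_d` gives a step-invariant gradient measure in mm/Gy.
#'
#' @param ddgi_mm raw shell distance in mm.
#' @param delta_d dose step in Gy (positive).
#' @return normalised index in mm/Gy.
#' @export
normalize_ddgi <- function(ddgi_mm, delta_d) {
  stopifnot(delta_d > 0)
  ddgi_mm / delta_d
}

#' Cumulative dose gradient index
#'
#' For each level i at or below the reference dose, sums the shell dDGI
#' values from i up to the shell ending at D0; exactly 0 at D0 and
#' non-decreasing as the level decreases. Levels above D0 get `NA`.
#'
#' @param level_table a data frame with columns `dose_gy` and `ddgi_mm`
#'   on a contiguous level grid (as built by [dgc_table()]).
#' @param d0_gy the reference (prescription) dose; must be one of the
#'   levels.
#' @param delta_d the intended level step in Gy, used to verify that no
#'   shells are missing; defaults to the table's `delta_d` attribute or,
#'   failing that, the median level spacing.
#' @return numeric vector of cDGI values (mm) aligned with the table rows.
#' @export
cdgi <- function(level_table, d0_gy,
                 delta_d = attr(level_table, "delta_d")) {
  doses <- level_table$dose_gy
  delta <- delta_d %||% stats::median(diff(doses))
  if (max(abs(diff(doses) - delta)) > 1e-6 * delta) {
    stop("level table is not contiguous: missing shells between levels")
  }
  i0 <- which(abs(doses - d0_gy) < 1e-6 * delta)
  if (length(i0) != 1L) stop("reference dose is not a level of the table")
  out <- rep(NA_real_, length(doses))
  out[i0] <- 0
  if (i0 > 1L) {
    # cDGI at level i sums shells [i, i+1], ..., [i0-1, i0]
    out[seq_len(i0 - 1L)] <- rev(cumsum(rev(level_table$ddgi_mm[seq_len(i0 - 1L)])))
  }
  out
}

#' Compute the dose gradient curve table
#'
#' The central per-isodose-level record: dose, relative dose, enclosed
#' volume V(d), surface area S(d), shell dDGI (anchored at d, i.e. the
#' shell between d and d + delta), step-normalised dDGI, and cumulative
#' cDGI. Surface areas use triangulated isosurface extraction from the
#' continuous dose field by default, or six-connectivity voxel face
#' counting (`surface_method = "voxel"`).
#'
#' Levels above the prescription whose isodose mask is empty terminate
#' the table upward; shells with zero mean surface are flagged `NaN` and
#' excluded from [min_ddgi()].
#'
#' @param dose_grid a [dose_grid()].
#' @param rx_gy prescription (reference) dose in Gy.
#' @inheritParams generate_dose_levels
#' @param surface_method `"marching_cubes"` (default) or `"voxel"`.
#' @param correction_factor passed to [surface_area_voxel()].
#' @return a `dgc_table` data frame with columns `dose_gy`, `rel_pct`,
#'   `volume_mm3`, `surface_mm2`, `ddgi_mm`, `ddgi_norm`, `cdgi_mm`;
#'   attributes `rx_gy`, `delta_d`, `spacing`, `surface_method`.
#' @export
dgc_table <- function(dose_grid, rx_gy, step = 1,
                      step_unit = c("percent", "Gy"), low_frac = 0.3,
                      surface_method = c("marching_cubes", "voxel"),
                      correction_factor = 1.0) {
  step_unit <- match.arg(step_unit)
  surface_method <- match.arg(surface_method)
  dmax <- max(dose_grid$values)
  if (rx_gy > dmax) {
    stop("prescription dose ", rx_gy, " Gy exceeds the maximum dose ",
         signif(dmax, 4), " Gy")
  }
  levels <- generate_dose_levels(rx_gy, step, step_unit, low_frac, dmax)
  delta <- attr(levels, "delta_d")
  voxvol <- prod(dose_grid$spacing)

  counts <- vapply(levels, function(d) sum(dose_grid$values >= d), numeric(1))
  # terminate the table upward at the first empty level above Rx
  keep <- counts > 0
  i_rx <- which(abs(levels - rx_gy) < 1e-6 * delta)
  if (!keep[i_rx]) stop("prescription isodose mask is empty")
  last <- i_rx
  while (last < length(levels) && keep[last + 1L]) last <- last + 1L
  levels <- levels[seq_len(last)]
  counts <- counts[seq_len(last)]
  vols <- counts * voxvol

  surf <- vapply(levels, function(d) {
    if (surface_method == "marching_cubes") {
      surface_area_marching_cubes(dose_grid$values, dose_grid$spacing,
                                  level = d)
    } else {
      surface_area_voxel(dose_grid$values >= d, dose_grid$spacing,
                         correction_factor)
    }
  }, numeric(1))

  n <- length(levels)
  dd <- rep(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    s_mean <- (surf[i] + surf[i + 1L]) / 2
    dd[i] <- if (s_mean > 0) (vols[i] - vols[i + 1L]) / s_mean else NaN
  }
  tab <- data.frame(
    dose_gy = levels,
    rel_pct = 100 * levels / rx_gy,
    volume_mm3 = vols,
    surface_mm2 = surf,
    ddgi_mm = dd,
    ddgi_norm = dd / delta
  )
  tab$cdgi_mm <- cdgi(tab, rx_gy)
  structure(tab, rx_gy = rx_gy, delta_d = delta,
            spacing = dose_grid$spacing, surface_method = surface_method,
            class = c("dgc_table", "data.frame"))
}

#' dDGI at the prescription dose
#'
#' Returns the dDGI of the shell anchored at the prescription level, i.e.
#' the shell between Rx and Rx + delta. When that shell is unavailable
#' (the Rx + delta mask is empty or Rx is the topmost level), the shell
#' below the prescription is used instead and the result carries
#' `attr(, "rx_shell") == "below"` together with a warning.
#'
#' @param level_table a [dgc_table()].
#' @param rx_gy prescription dose; defaults to the table's `rx_gy`
#'   attribute.
#' @return dDGI in mm with attribute `rx_shell` (`"above"` or `"below"`).
#' @export
ddgi_at_rx <- function(level_table, rx_gy = attr(level_table, "rx_gy")) {
  delta <- attr(level_table, "delta_d") %||%
    stats::median(diff(level_table$dose_gy))
  i <- which(abs(level_table$dose_gy - rx_gy) < 1e-6 * delta)
  if (length(i) != 1L) stop("prescription level not present in the table")
  val <- level_table$ddgi_mm[i]
  if (is.na(val)) {
    if (i == 1L) stop("no shell adjacent to the prescription level")
    warning("shell above the prescription unavailable; ",
            "using the shell below Rx")
    return(structure(level_table$ddgi_mm[i - 1L], rx_shell = "below"))
  }
  structure(val, rx_shell = "above")
}

#' Minimum dDGI over all computed shells
#'
#' Shells flagged `NaN` (zero mean surface) and the table's trailing
#' shell-less level are excluded.
#'
#' @inheritParams ddgi_at_rx
#' @return minimum shell distance in mm.
#' @export
min_ddgi <- function(level_table) {
  v <- level_table$ddgi_mm
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("no valid shells in the table")
  min(v)
}

.GRADE_THRESHOLDS <- c(Ideal = 3, Good = 5, Acceptable = 7)

.GRADE_TEXT <- c(
  Ideal = paste("Steep dose fall-off typical of small-volume SRS plans;",
                "no gradient-related action indicated."),
  Good = paste("Dose fall-off commonly observed in standard SBRT plans;",
               "gradient is clinically adequate."),
  Acceptable = paste("Gradient consistent with larger targets or",
                     "low-density tissue (e.g. lung); review OAR proximity."),
  Poor = paste("Shallow dose gradient; plan re-optimization may be",
               "warranted if organs at risk are nearby.")
)

#' Clinical quality grade of the dose gradient
#'
#' Four-tier grading of the dDGI at the prescription dose: Ideal (< 3 mm),
#' Good (3 to < 5 mm), Acceptable (5 to < 7 mm), Poor (>= 7 mm). Band
#' boundaries are lower-inclusive.
#'
#' @param ddgi_at_rx_mm finite non-negative dDGI at the prescription, mm.
#' @return a `dgc_grade`: `list(grade =, ddgi_at_rx_mm =, interpretation =)`.
#' @export
grade <- function(ddgi_at_rx_mm) {
  x <- as.numeric(ddgi_at_rx_mm)
  if (!is.finite(x) || x < 0) {
    stop("dDGI at the prescription must be finite and non-negative")
  }
  g <- if (x < 3) "Ideal" else if (x < 5) "Good" else if (x < 7) {
    "Acceptable"
  } else "Poor"
  structure(list(grade = g, ddgi_at_rx_mm = x,
                 interpretation = unname(.GRADE_TEXT[g])),
            class = "dgc_grade")
}

#' @export
print.dgc_grade <- function(x, ...) {
  cat(sprintf("Dose gradient grade: %s (dDGI at Rx = %.3f mm)\n  %s\n",
              x$grade, x$ddgi_at_rx_mm, x$interpretation))
  invisible(x)
}
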