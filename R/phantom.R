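# Synthetic spherical phantoms with closed-form isodose geometry: the
# validation oracle for the whole pipeline. A radially symmetric dose
# field falls off linearly at g Gy/mm around a spherical target of radius
# r0 carrying the prescription d0 at its surface, so every isodose radius
# is known exactly: r(d) = r0 + (d0 - d) / g.

#' Specify a spherical dose phantom
#'
#' The default profile (`"linear_peak"`) continues the linear fall-off
#' inward through the target surface and plateaus only in a small core
#' (radius `r0/2`), giving a dose peak of `d0 + g*r0/2` like a clinical
#' SRS plan prescribed to a sub-maximum isodose; every level between 0
#' and the peak then has the closed-form radius above. The `"plateau"`
#' variant holds the dose at exactly `d0` everywhere inside the target,
#' so no level above the prescription exists and the shell at Rx falls
#' back to the one below it.
#'
#' @param r0_mm target radius in mm (positive).
#' @param d0_gy plateau/prescription dose in Gy (default 13, a typical
#'   vestibular-schwannoma SRS prescription).
#' @param g_gy_per_mm radial fall-off slope in Gy/mm; the default puts
#'   the half-prescription isodose 3 mm outside the target (the classic
#'   SRS optimum-gradient distance), i.e. `g = d0/6`.
#' @param spacing_mm isotropic voxel spacing in mm (default 1, matching
#'   clinical SRS dose grids).
#' @param extent_mm cubic grid edge length in mm; defaults to enclosing
#'   the `low_frac` isodose sphere with a 3 mm margin.
#' @param center_mm sphere centre in patient coordinates (mm).
#' @param low_frac lowest analyzed isodose fraction used to size the
#'   default extent (default 0.3).
#' @param seed integer seed recorded in the spec; all derived DICOM UIDs
#'   are deterministic functions of it.
#' @param profile `"linear_peak"` (default) or `"plateau"`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(r0_mm = 10, d0_gy = 13, g_gy_per_mm = d0_gy / 6,
                         spacing_mm = 1, extent_mm = NULL,
                         center_mm = c(0, 0, 0), low_frac = 0.3,
                         seed = 1L, profile = c("linear_peak", "plateau")) {
  profile <- match.arg(profile)
  stopifnot(r0_mm > 0, d0_gy > 0, g_gy_per_mm > 0, spacing_mm > 0)
  r_low <- r0_mm + (1 - low_frac) * d0_gy / g_gy_per_mm
  if (is.null(extent_mm)) extent_mm <- 2 * (r_low + 3)
  if (extent_mm / 2 < r_low) {
    stop("grid extent ", extent_mm, " mm cannot contain the ",
         round(100 * low_frac), "% isodose sphere (radius ",
         signif(r_low, 4), " mm)")
  }
  structure(list(r0_mm = r0_mm, d0_gy = d0_gy, g_gy_per_mm = g_gy_per_mm,
                 spacing_mm = spacing_mm, extent_mm = extent_mm,
                 center_mm = as.numeric(center_mm), low_frac = low_frac,
                 seed = as.integer(seed), profile = profile),
            class = "phantom_spec")
}

.phantom_dose_of_r <- function(r, spec) {
  d <- spec$d0_gy + spec$g_gy_per_mm * (spec$r0_mm - r)
  if (spec$profile == "plateau") {
    d <- pmin(d, spec$d0_gy)
  } else {
    d <- pmin(d, spec$d0_gy + spec$g_gy_per_mm * spec$r0_mm / 2)
  }
  pmax(d, 0)
}

# grid axes snap to the spacing lattice, so a sub-voxel center_mm offsets
# the sphere relative to the voxel lattice (avoids the aligned worst case)
.phantom_axes <- function(spec) {
  n <- max(3L, floor(spec$extent_mm / spec$spacing_mm) + 1L)
  lapply(1:3, function(a) {
    gc <- round(spec$center_mm[a] / spec$spacing_mm) * spec$spacing_mm
    gc + (seq_len(n) - (n + 1) / 2) * spec$spacing_mm
  })
}

#' Generate a spherical dose phantom
#'
#' Builds the analytic dose field on the grid, a polygonal target ROI
#' (64 vertices per plane approximating the `r0` sphere), and the plan
#' information carrying the prescription `d0`.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_bundle`: `list(dose =, roi =, plan =, spec =)`.
#' @export
make_sphere_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- .phantom_axes(spec)
  n <- length(ax[[1]])
  dx2 <- (ax[[1]] - spec$center_mm[1])^2
  dy2 <- (ax[[2]] - spec$center_mm[2])^2
  dz2 <- (ax[[3]] - spec$center_mm[3])^2
  r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  values <- array(.phantom_dose_of_r(r, spec), dim = c(n, n, n))
  grid <- dose_grid(values, spacing = rep(spec$spacing_mm, 3),
                    origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
  roi <- .sphere_roi(spec, ax[[3]])
  plan <- list(rx_gy = spec$d0_gy, n_fractions = 1L, source = "plan_file")
  structure(list(dose = grid, roi = roi, plan = plan, spec = spec),
            class = "phantom_bundle")
}

# polygonal approximation of the r0 sphere: one 64-gon per dose slice
.sphere_roi <- function(spec, slice_z, n_vertices = 64L, name = "Target") {
  contours <- list()
  for (z in slice_z) {
    h <- z - spec$center_mm[3]
    if (abs(h) >= spec$r0_mm) next
    rho <- sqrt(spec$r0_mm^2 - h^2)
    if (rho < 1e-3) next
    th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
    contours[[length(contours) + 1L]] <- list(
      z = z,
      xy = cbind(spec$center_mm[1] + rho * cos(th),
                 spec$center_mm[2] + rho * sin(th)))
  }
  structure(list(name = name, number = 1L, contours = contours),
            class = "roi")
}

#' Closed-form isodose geometry of a phantom
#'
#' The analytic quantities every oracle test compares against: isodose
#' radius, enclosed volume and surface area as functions of dose, shell
#' distance per step, cumulative fall-off distance, and the gradient
#' index with its cube-law form `(1 + d_f/r0)^3`.
#'
#' @param spec a [phantom_spec()].
#' @return a list of closed forms: functions `r_of_d(d)`, `v_of_d(d)`,
#'   `s_of_d(d)`, `ddgi(delta_d)`, `cdgi_at(d)`, and scalars `fall_off_mm`
#'   (prescription to half-prescription distance) and `gi`.
#' @export
analytic_truth <- function(spec) {
  r0 <- spec$r0_mm; d0 <- spec$d0_gy; g <- spec$g_gy_per_mm
  r_of_d <- function(d) r0 + (d0 - d) / g
  list(
    r_of_d = r_of_d,
    v_of_d = function(d) 4 / 3 * pi * r_of_d(d)^3,
    s_of_d = function(d) 4 * pi * r_of_d(d)^2,
    ddgi = function(delta_d) delta_d / g,
    cdgi_at = function(d) (d0 - d) / g,
    fall_off_mm = 0.5 * d0 / g,
    gi = (1 + 0.5 * d0 / g / r0)^3
  )
}

#' Merge several sphere phantoms into one multi-target phantom
#'
#' The dose is the voxelwise maximum of the component fields on a common
#' grid; analytic truth stays valid (volumes and surfaces additive) while
#' the component isodose surfaces at the lowest analyzed level remain
#' disjoint, which is enforced as a precondition.
#'
#' @param specs list of [phantom_spec()]s sharing spacing; each spec's
#'   `center_mm` places its sphere.
#' @return a `phantom_bundle` whose `roi` field is a list of target ROIs
#'   and whose `truth` attribute gives the additive closed forms.
#' @export
make_multisphere_phantom <- function(specs) {
  stopifnot(length(specs) >= 2L)
  sp <- vapply(specs, function(s) s$spacing_mm, numeric(1))
  if (max(sp) - min(sp) > 1e-9) stop("component spacings must match")
  r_low <- vapply(specs, function(s) {
    s$r0_mm + (1 - s$low_frac) * s$d0_gy / s$g_gy_per_mm
  }, numeric(1))
  ctr <- t(vapply(specs, function(s) s$center_mm, numeric(3)))
  for (a in seq_along(specs)) {
    for (b in seq_len(a - 1L)) {
      gap <- sqrt(sum((ctr[a, ] - ctr[b, ])^2))
      if (gap <= r_low[a] + r_low[b]) {
        stop("spheres ", b, " and ", a, " overlap at the lowest analyzed ",
             "isodose (separation ", signif(gap, 4), " mm <= ",
             signif(r_low[a] + r_low[b], 4), " mm)")
      }
    }
  }
  lo <- apply(ctr - r_low - 3, 2, min)
  hi <- apply(ctr + r_low + 3, 2, max)
  s1 <- specs[[1]]
  axes <- lapply(1:3, function(a) {
    seq(lo[a], hi[a] + s1$spacing_mm / 2, by = s1$spacing_mm)
  })
  dims <- vapply(axes, length, integer(1))
  values <- array(0, dim = dims)
  for (s in specs) {
    dx2 <- (axes[[1]] - s$center_mm[1])^2
    dy2 <- (axes[[2]] - s$center_mm[2])^2
    dz2 <- (axes[[3]] - s$center_mm[3])^2
    r <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
    values <- pmax(values, array(.phantom_dose_of_r(r, s), dim = dims))
  }
  grid <- dose_grid(values, spacing = rep(s1$spacing_mm, 3),
                    origin = c(axes[[1]][1], axes[[2]][1], axes[[3]][1]))
  rois <- lapply(seq_along(specs), function(a) {
    roi <- .sphere_roi(specs[[a]], axes[[3]],
                       name = paste0("Target", a))
    roi$number <- a
    roi
  })
  truths <- lapply(specs, analytic_truth)
  truth <- list(
    v_of_d = function(d) sum(vapply(truths, function(t) t$v_of_d(d),
                                    numeric(1))),
    s_of_d = function(d) sum(vapply(truths, function(t) t$s_of_d(d),
                                    numeric(1)))
  )
  structure(list(dose = grid, roi = rois,
                 plan = list(rx_gy = s1$d0_gy, n_fractions = 1L,
                             source = "plan_file"),
                 spec = specs),
            truth = truth, class = "phantom_bundle")
}

# deterministic UID derived from the spec seed
.phantom_uid <- function(seed, kind) {
  paste0("1.2.826.0.1.3680043.10.1448.", kind, ".",
         as.integer(seed) %% 100000L)
}

#' Write a phantom bundle as a DICOM RT triplet
#'
#' Emits standards-conformant RT Dose (16-bit pixel data with a
#' `DoseGridScaling` giving quantisation below 0.01% of the prescription),
#' RT Structure Set, and RT Plan (with the prescription in
#' `DoseReferenceSequence`). Output is byte-deterministic for a given
#' spec and seed.
#'
#' @param bundle a `phantom_bundle` from [make_sphere_phantom()].
#' @param directory output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_dicom_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  seed <- if (inherits(bundle$spec, "phantom_spec")) bundle$spec$seed else 1L
  grid <- bundle$dose
  d <- dim(grid$values)
  dmax <- max(grid$values)
  scaling <- dmax / 60000
  stored <- as.integer(round(grid$values / scaling))
  common <- list(
    "0008,0020" = list(vr = "DA", value = "20260101"),
    "0008,0030" = list(vr = "TM", value = "000000"),
    "0010,0010" = list(vr = "PN", value = "Phantom^Synthetic"),
    "0010,0020" = list(vr = "LO", value = sprintf("PHANTOM%05d", seed)),
    "0010,0040" = list(vr = "CS", value = "O"),
    "0020,000D" = list(vr = "UI", value = .phantom_uid(seed, 1)),
    "0020,000E" = list(vr = "UI", value = .phantom_uid(seed, 2))
  )

  dose_el <- c(common, list(
    "0008,0016" = list(vr = "UI", value = UID_RT_DOSE),
    "0008,0018" = list(vr = "UI", value = .phantom_uid(seed, 3)),
    "0008,0060" = list(vr = "CS", value = "RTDOSE"),
    "0020,0032" = list(vr = "DS", value = grid$origin),
    "0020,0037" = list(vr = "DS", value = c(1, 0, 0, 0, 1, 0)),
    "0028,0002" = list(vr = "US", value = 1L),
    "0028,0004" = list(vr = "CS", value = "MONOCHROME2"),
    "0028,0008" = list(vr = "IS", value = d[3]),
    "0028,0010" = list(vr = "US", value = d[2]),           # rows (y)
    "0028,0011" = list(vr = "US", value = d[1]),           # columns (x)
    "0028,0030" = list(vr = "DS", value = grid$spacing[c(2, 1)]),
    "0028,0100" = list(vr = "US", value = 16L),
    "0028,0101" = list(vr = "US", value = 16L),
    "0028,0102" = list(vr = "US", value = 15L),
    "0028,0103" = list(vr = "US", value = 0L),
    "3004,0002" = list(vr = "CS", value = "GY"),
    "3004,0004" = list(vr = "CS", value = "PHYSICAL"),
    "3004,000A" = list(vr = "CS", value = "PLAN"),
    "3004,000C" = list(vr = "DS", value = grid$slice_offsets),
    "3004,000E" = list(vr = "DS", value = scaling),
    "7FE0,0010" = list(vr = "OW",
                       value = writeBin(stored, raw(), size = 2L,
                                        endian = "little"))
  ))

  rois <- if (inherits(bundle$roi, "roi")) list(bundle$roi) else bundle$roi
  roi_defs <- lapply(seq_along(rois), function(a) {
    list("3006,0022" = list(vr = "IS", value = a),
         "3006,0026" = list(vr = "LO", value = rois[[a]]$name),
         "3006,0024" = list(vr = "UI", value = .phantom_uid(seed, 2)))
  })
  roi_contours <- lapply(seq_along(rois), function(a) {
    items <- lapply(rois[[a]]$contours, function(ct) {
      pts <- as.numeric(t(cbind(ct$xy, ct$z)))
      list("3006,0042" = list(vr = "CS", value = "CLOSED_PLANAR"),
           "3006,0046" = list(vr = "IS", value = nrow(ct$xy)),
           "3006,0050" = list(vr = "DS", value = pts))
    })
    list("3006,0084" = list(vr = "IS", value = a),
         "3006,0040" = list(vr = "SQ", value = items))
  })
  struct_el <- c(common, list(
    "0008,0016" = list(vr = "UI", value = UID_RT_STRUCT),
    "0008,0018" = list(vr = "UI", value = .phantom_uid(seed, 4)),
    "0008,0060" = list(vr = "CS", value = "RTSTRUCT"),
    "3006,0002" = list(vr = "SH", value = "PhantomStructs"),
    "3006,0020" = list(vr = "SQ", value = roi_defs),
    "3006,0039" = list(vr = "SQ", value = roi_contours)
  ))

  plan_el <- c(common, list(
    "0008,0016" = list(vr = "UI", value = UID_RT_PLAN),
    "0008,0018" = list(vr = "UI", value = .phantom_uid(seed, 5)),
    "0008,0060" = list(vr = "CS", value = "RTPLAN"),
    "300A,0002" = list(vr = "SH", value = "PhantomPlan"),
    "300A,0010" = list(vr = "SQ", value = list(list(
      "300A,0014" = list(vr = "CS", value = "SITE"),
      "300A,0020" = list(vr = "CS", value = "TARGET"),
      "300A,0026" = list(vr = "DS", value = bundle$plan$rx_gy)
    ))),
    "300A,0070" = list(vr = "SQ", value = list(list(
      "300A,0078" = list(vr = "IS",
                         value = bundle$plan$n_fractions %||% 1L)
    )))
  ))

  paths <- c(
    dose = file.path(directory, "rtdose.dcm"),
    struct = file.path(directory, "rtstruct.dcm"),
    plan = file.path(directory, "rtplan.dcm"))
  dcm_write(dose_el, paths["dose"], UID_RT_DOSE, .phantom_uid(seed, 3))
  dcm_write(struct_el, paths["struct"], UID_RT_STRUCT, .phantom_uid(seed, 4))
  dcm_write(plan_el, paths["plan"], UID_RT_PLAN, .phantom_uid(seed, 5))
  paths
}
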