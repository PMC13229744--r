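# Isodose masks and the volume / surface-area estimators V(d), S(d) that
# feed the dose gradient formulas.

#' Binary isodose mask
#'
#' A voxel is included iff its dose is at or above the threshold
#' (inclusive), so masks are nested: the mask at a lower level contains
#' every mask at a higher level.
#'
#' @param dose_grid a [dose_grid()].
#' @param level_gy dose threshold in Gy (non-negative).
#' @return an `isodose_mask`: `list(mask = <logical 3D array>, level_gy =,
#'   spacing =)`.
#' @export
isodose_mask <- function(dose_grid, level_gy) {
  stopifnot(level_gy >= 0)
  structure(list(mask = dose_grid$values >= level_gy,
                 level_gy = level_gy, spacing = dose_grid$spacing),
            class = "isodose_mask")
}

.mask_and_spacing <- function(mask, spacing) {
  if (inherits(mask, "isodose_mask")) {
    list(mask = mask$mask, spacing = mask$spacing)
  } else {
    stopifnot(!is.null(spacing), length(dim(mask)) == 3L)
    list(mask = mask, spacing = as.numeric(spacing))
  }
}

#' Enclosed volume of a mask
#'
#' Voxel-counting volume: the number of included voxels times the voxel
#' volume. An empty mask has volume 0.
#'
#' @param mask an [isodose_mask()] or a logical 3D array.
#' @param spacing voxel spacing in mm (ignored for an `isodose_mask`).
#' @return volume in mm^3.
#' @export
enclosed_volume <- function(mask, spacing = NULL) {
  ms <- .mask_and_spacing(mask, spacing)
  sum(ms$mask) * prod(ms$spacing)
}

#' Isosurface area by triangulated isosurface extraction
#'
#' Extracts a triangulated isosurface from a 3D scalar field by marching
#' tetrahedra (each grid cell split into six tetrahedra with linear edge
#' interpolation -- the unambiguous refinement of the marching cubes
#' family) and sums the exact triangle areas. The field is virtually
#' zero-padded by one layer on every face so that surfaces touching the
#' grid edge are closed.
#'
#' For a logical mask the extraction runs at the 0.5 level of the 0/1
#' field; note that on binary input the vertices can only fall at edge
#' midpoints, which carries a resolution-independent lattice bias on
#' curved surfaces (several percent overestimate for spheres). Passing
#' the continuous dose field with `level` set to the isodose value uses
#' sub-voxel interpolation and is accurate to a fraction of a percent;
#' the DGC pipeline does the latter.
#'
#' @param field a numeric 3D array (e.g. a dose grid's values), a logical
#'   3D array, or an [isodose_mask()].
#' @param spacing voxel spacing in mm.
#' @param level iso-level at which to extract (default 0.5, the convention
#'   for binary masks).
#' @return surface area in mm^2; 0 with a warning when no surface exists.
#' @export
surface_area_marching_cubes <- function(field, spacing = NULL, level = 0.5) {
  if (inherits(field, "isodose_mask")) {
    spacing <- field$spacing
    field <- field$mask
    level <- 0.5
  }
  if (inherits(field, "dose_grid")) {
    spacing <- field$spacing
    field <- field$values
  }
  stopifnot(length(dim(field)) == 3L, length(spacing) == 3L)
  vals <- as.numeric(field)
  if (!any(vals >= level)) {
    warning("no surface exists at level ", level)
    return(0)
  }
  .mt_surface_area(vals, dim(field), as.numeric(spacing),
                   as.numeric(level), 0)
}

#' Isosurface area by voxel face counting
#'
#' Counts exposed faces of the binary mask (an included voxel adjacent to
#' an excluded or outside voxel along +-x, +-y, +-z), sums their physical
#' areas, and multiplies by `correction_factor`. The raw exposed-face area
#' of a smooth surface exceeds the true area by the Manhattan-surface
#' bias (a factor of 1.5 for a sphere); the correction factor is exposed
#' so callers can emulate corrected variants.
#'
#' @inheritParams enclosed_volume
#' @param correction_factor multiplier applied to the raw face area
#'   (default 1.0).
#' @return surface area in mm^2.
#' @export
surface_area_voxel <- function(mask, spacing = NULL, correction_factor = 1.0) {
  ms <- .mask_and_spacing(mask, spacing)
  correction_factor * .voxel_face_area(ms$mask, dim(ms$mask), ms$spacing)
}

#' Structure volume from contours (shoelace formula)
#'
#' Per-plane polygon areas by the shoelace formula; multiple polygons on
#' one plane are combined by even-odd parity, so a polygon nested inside
#' another (a hole) subtracts. The plane areas are summed and multiplied
#' by the inter-slice thickness inferred from the distinct plane
#' coordinates.
#'
#' @param roi an `roi` object (see [load_structures()]).
#' @param thickness inter-slice thickness in mm; required for a
#'   single-plane ROI, otherwise inferred from consecutive plane spacing.
#' @return volume in mm^3.
#' @export
contour_volume_shoelace <- function(roi, thickness = NULL) {
  stopifnot(length(roi$contours) >= 1L)
  zs <- vapply(roi$contours, function(ct) ct$z, numeric(1))
  planes <- sort(unique(round(zs, 6)))
  if (is.null(thickness)) {
    if (length(planes) < 2L) {
      stop("single-plane ROI: supply the inter-slice `thickness` explicitly")
    }
    thickness <- min(diff(planes))
  }
  plane_area <- vapply(planes, function(z) {
    idx <- which(abs(zs - z) < 1e-6)
    areas <- vapply(roi$contours[idx],
                    function(ct) .shoelace_area(ct$xy), numeric(1))
    if (length(areas) == 1L) return(areas)
    # even-odd parity: a polygon contained in another subtracts
    signs <- vapply(seq_along(idx), function(a) {
      depth <- sum(vapply(seq_along(idx), function(b) {
        if (a == b) return(FALSE)
        .polygon_contains(roi$contours[[idx[b]]]$xy,
                          roi$contours[[idx[a]]]$xy[1, ])
      }, logical(1)))
      if (depth %% 2 == 0) 1 else -1
    }, numeric(1))
    sum(signs * areas)
  }, numeric(1))
  sum(plane_area) * thickness
}

.shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.polygon_contains <- function(poly, pt) {
  as.logical(.points_in_polygons(matrix(pt, ncol = 2), list(poly), 1e-9))
}
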