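# DICOM RT object ingestion: classification by SOP Class UID, dose grid
# extraction (DoseGridScaling, PixelSpacing, GridFrameOffsetVector), ROI
# contour extraction, and prescription resolution.

#' Construct a dose grid
#'
#' The internal 3D dose representation: physical dose values in Gy on a
#' regular grid in patient coordinates. Voxel `[i, j, k]` is centred at
#' `origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz)`.
#'
#' @param values 3D numeric array of dose in Gy, dimensions (x, y, z).
#' @param spacing voxel spacing `c(dx, dy, dz)` in mm, strictly positive.
#' @param origin patient-coordinate position (mm) of the first voxel centre.
#' @param slice_offsets per-slice z offsets (mm) relative to the first
#'   slice; must be strictly monotone and uniformly spaced.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0),
                      slice_offsets = NULL) {
  stopifnot(length(dim(values)) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (any(values < 0)) stop("dose values must be non-negative")
  if (is.null(slice_offsets)) {
    slice_offsets <- (seq_len(dim(values)[3]) - 1) * spacing[3]
  }
  .check_slice_offsets(slice_offsets, spacing[3])
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         slice_offsets = as.numeric(slice_offsets)),
    class = "dose_grid")
}

# slice offsets must be strictly monotone and uniform to 0.01 mm
.check_slice_offsets <- function(offsets, dz) {
  if (length(offsets) > 1L) {
    d <- diff(offsets)
    if (!(all(d > 0) || all(d < 0))) {
      stop("slice offsets are not strictly monotone")
    }
    if (max(abs(abs(d) - dz)) > 0.01) {
      stop("non-uniform slice offsets (beyond 0.01 mm tolerance)")
    }
  }
  invisible(TRUE)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  dose range %.4g - %.4g Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Classify a DICOM RT file by SOP Class UID
#'
#' @param path path to a DICOM file.
#' @return one of `"DOSE"`, `"STRUCT"`, `"PLAN"`, `"UNSUPPORTED"`.
#'   A non-DICOM file raises a parse error naming the file; an
#'   unrecognised SOP class is reported as `"UNSUPPORTED"`, never an error,
#'   so that batch runs can skip it.
#' @export
classify_rt_file <- function(path) {
  ds <- dcm_read(path)
  uid <- dcm_get(ds, "0008,0016")
  if (is.null(uid)) return("UNSUPPORTED")
  switch(uid,
    "1.2.840.10008.5.1.4.1.1.481.2" = "DOSE",
    "1.2.840.10008.5.1.4.1.1.481.3" = "STRUCT",
    "1.2.840.10008.5.1.4.1.1.481.5" = "PLAN",
    "UNSUPPORTED")
}

#' Load a DICOM RT Dose file
#'
#' Extracts the 3D dose array from the pixel data, converts stored values
#' to physical dose in Gy via `DoseGridScaling`, and populates the grid
#' geometry from `PixelSpacing`, `ImagePositionPatient` and
#' `GridFrameOffsetVector`.
#'
#' @param path path to an RT Dose file.
#' @return a [dose_grid()] with patient demographics (if present) attached
#'   as the `"patient"` attribute.
#' @export
load_dose <- function(path) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "0008,0016"), UID_RT_DOSE)) {
    stop("not an RT Dose object: ", path)
  }
  scaling <- dcm_get(ds, "3004,000E")
  if (is.null(scaling)) stop("RT Dose file lacks DoseGridScaling: ", path)
  rows <- dcm_get(ds, "0028,0010")
  cols <- dcm_get(ds, "0028,0011")
  nframes <- dcm_get(ds, "0028,0008", default = 1)
  bits <- dcm_get(ds, "0028,0100", default = 16L)
  px_spacing <- dcm_get(ds, "0028,0030")   # (row spacing = dy, col spacing = dx)
  ipp <- dcm_get(ds, "0020,0032", default = c(0, 0, 0))
  offsets <- dcm_get(ds, "3004,000C")
  if (is.null(offsets)) stop("RT Dose file lacks GridFrameOffsetVector: ", path)
  if (length(offsets) != nframes) {
    stop("GridFrameOffsetVector length does not match NumberOfFrames")
  }
  dz <- if (length(offsets) > 1L) abs(diff(offsets)[1]) else 1
  .check_slice_offsets(offsets, dz)

  px <- ds[["7FE0,0010"]]$value
  n <- cols * rows * nframes
  stored <- if (bits == 32L) {
    readBin(px, "integer", n = n, size = 4L, endian = "little")
  } else {
    readBin(px, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  }
  # pixel order: column (x) fastest, then row (y), then frame (z)
  values <- array(stored * scaling, dim = c(cols, rows, nframes))
  g <- dose_grid(values,
                 spacing = c(px_spacing[2], px_spacing[1], dz),
                 origin = ipp, slice_offsets = offsets)
  attr(g, "patient") <- .patient_info(ds)
  g
}

.patient_info <- function(ds) {
  list(name = dcm_get(ds, "0010,0010"), id = dcm_get(ds, "0010,0020"),
       sex = dcm_get(ds, "0010,0040"), age = dcm_get(ds, "0010,1010"))
}

#' Load a DICOM RT Structure Set
#'
#' Extracts every ROI's name and planar contour polygons. Contours with
#' fewer than 3 vertices are rejected with a warning. When a dose grid is
#' supplied, ROIs whose contours fall entirely outside the grid are
#' flagged (`out_of_grid = TRUE`), not dropped.
#'
#' @param path path to an RT Structure Set file.
#' @param dose_grid optional [dose_grid()] for the spatial consistency check.
#' @return a list of `roi` objects, each with fields `name`, `number` and
#'   `contours` (a list of `list(z =, xy = )` planar polygons; `xy` is an
#'   n x 2 matrix of vertex coordinates in mm).
#' @export
load_structures <- function(path, dose_grid = NULL) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "0008,0016"), UID_RT_STRUCT)) {
    stop("not an RT Structure Set object: ", path)
  }
  roi_defs <- dcm_get(ds, "3006,0020", default = list())
  names_by_number <- list()
  for (item in roi_defs) {
    num <- item[["3006,0022"]]$value
    names_by_number[[as.character(num)]] <-
      item[["3006,0026"]]$value %||% paste0("ROI", num)
  }
  contour_sets <- dcm_get(ds, "3006,0039", default = list())
  rois <- lapply(contour_sets, function(item) {
    num <- item[["3006,0084"]]$value
    name <- names_by_number[[as.character(num)]] %||% paste0("ROI", num)
    contours <- list()
    for (ct in (item[["3006,0040"]]$value %||% list())) {
      pts <- ct[["3006,0050"]]$value
      if (is.null(pts)) next
      m <- matrix(pts, ncol = 3L, byrow = TRUE)
      if (nrow(m) < 3L) {
        warning("ROI '", name, "': contour with fewer than 3 vertices rejected")
        next
      }
      contours[[length(contours) + 1L]] <-
        list(z = m[1, 3], xy = m[, 1:2, drop = FALSE])
    }
    roi <- structure(list(name = name, number = num, contours = contours),
                     class = "roi")
    if (length(contours) == 0L) attr(roi, "empty") <- TRUE
    roi
  })
  if (!is.null(dose_grid)) {
    rois <- lapply(rois, function(roi) {
      attr(roi, "out_of_grid") <- .roi_out_of_grid(roi, dose_grid)
      roi
    })
  }
  rois
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.roi_out_of_grid <- function(roi, grid) {
  if (length(roi$contours) == 0L) return(TRUE)
  d <- dim(grid$values)
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (d - 1) * grid$spacing + grid$spacing / 2
  for (ct in roi$contours) {
    x <- ct$xy[, 1]; y <- ct$xy[, 2]; z <- ct$z
    if (any(x >= lo[1] & x <= hi[1]) && any(y >= lo[2] & y <= hi[2]) &&
        z >= lo[3] && z <= hi[3]) {
      return(FALSE)
    }
  }
  TRUE
}

#' Load a DICOM RT Plan
#'
#' Extracts the target prescription dose from `DoseReferenceSequence` and
#' the planned fraction count from `FractionGroupSequence`.
#'
#' @param path path to an RT Plan file.
#' @return `list(rx_gy =, n_fractions =)`; either field is `NULL` when the
#'   corresponding sequence lacks the entry.
#' @export
load_plan <- function(path) {
  ds <- dcm_read(path)
  if (!identical(dcm_get(ds, "0008,0016"), UID_RT_PLAN)) {
    stop("not an RT Plan object: ", path)
  }
  rx <- NULL
  for (item in dcm_get(ds, "300A,0010", default = list())) {
    v <- item[["300A,0026"]]$value
    if (!is.null(v)) { rx <- v; break }
  }
  nfx <- NULL
  for (item in dcm_get(ds, "300A,0070", default = list())) {
    v <- item[["300A,0078"]]$value
    if (!is.null(v)) { nfx <- as.integer(v); break }
  }
  list(rx_gy = rx, n_fractions = nfx)
}

#' Resolve the prescription dose
#'
#' Precedence: an explicit user override, then the RT Plan's target
#' prescription, then an estimate of 5/6 of the maximum dose (about the
#' 83% isodose level, the common SRS/SABR prescription convention).
#'
#' @param plan an RT Plan file path, the result of [load_plan()], or `NULL`.
#' @param dose_grid the companion [dose_grid()] (required for estimation).
#' @param user_rx optional user-supplied prescription in Gy.
#' @return `list(rx_gy =, n_fractions =, source =)` with `source` one of
#'   `"user"`, `"plan_file"`, `"estimated"`.
#' @export
resolve_prescription <- function(plan = NULL, dose_grid = NULL,
                                 user_rx = NULL) {
  if (!is.null(user_rx)) {
    stopifnot(user_rx > 0)
    return(list(rx_gy = as.numeric(user_rx), n_fractions = NULL,
                source = "user"))
  }
  if (!is.null(plan)) {
    p <- if (is.character(plan)) load_plan(plan) else plan
    if (!is.null(p$rx_gy) && p$rx_gy > 0) {
      return(list(rx_gy = as.numeric(p$rx_gy), n_fractions = p$n_fractions,
                  source = "plan_file"))
    }
    warning("RT Plan lacks a target prescription entry; ",
            "falling back to 5/6 of the maximum dose")
  }
  if (is.null(dose_grid)) {
    stop("no prescription available and no dose grid to estimate from")
  }
  list(rx_gy = 5 / 6 * max(dose_grid$values), n_fractions = NULL,
       source = "estimated")
}
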