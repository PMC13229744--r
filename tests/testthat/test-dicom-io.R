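# DICOM ingestion: classification, dose/structure/plan loading,
# prescription resolution.

test_that("RT files classify by SOP Class UID and bad input errors", {
  dir <- withr::local_tempdir()
  paths <- write_dicom_bundle(make_sphere_phantom(ph_spec(r0 = 6)), dir)
  expect_equal(classify_rt_file(paths["dose"]), "DOSE", ignore_attr = TRUE)
  expect_equal(classify_rt_file(paths["struct"]), "STRUCT",
               ignore_attr = TRUE)
  expect_equal(classify_rt_file(paths["plan"]), "PLAN", ignore_attr = TRUE)

  # a CT Image Storage object is reported, not fatal
  ct <- file.path(dir, "ct.dcm")
  dcm_write(list("0008,0016" = list(vr = "UI",
                                    value = "1.2.840.10008.5.1.4.1.1.2")),
            ct, "1.2.840.10008.5.1.4.1.1.2", "1.2.3.4")
  expect_equal(classify_rt_file(ct), "UNSUPPORTED")

  txt <- file.path(dir, "notes.txt")
  writeLines("not a dicom", txt)
  expect_error(classify_rt_file(txt), "not a DICOM.*notes.txt")
})

.mini_dose_file <- function(path, stored, scaling, offsets,
                            drop_scaling = FALSE) {
  n <- length(stored)
  el <- list(
    "0008,0016" = list(vr = "UI", value = rtdgc:::UID_RT_DOSE),
    "0020,0032" = list(vr = "DS", value = c(0, 0, 0)),
    "0028,0008" = list(vr = "IS", value = length(offsets)),
    "0028,0010" = list(vr = "US", value = 1L),
    "0028,0011" = list(vr = "US", value = n / length(offsets)),
    "0028,0030" = list(vr = "DS", value = c(1, 1)),
    "0028,0100" = list(vr = "US", value = 16L),
    "3004,000C" = list(vr = "DS", value = offsets),
    "3004,000E" = list(vr = "DS", value = scaling),
    "7FE0,0010" = list(vr = "OW",
                       value = writeBin(as.integer(stored), raw(),
                                        size = 2L, endian = "little"))
  )
  if (drop_scaling) el[["3004,000E"]] <- NULL
  dcm_write(el, path, rtdgc:::UID_RT_DOSE, "1.2.3.5")
  path
}

test_that("dose loading applies DoseGridScaling and grid geometry", {
  dir <- withr::local_tempdir()
  f <- .mini_dose_file(file.path(dir, "d.dcm"), stored = c(5000L, 0L, 1000L),
                       scaling = 1e-3, offsets = c(0, 2.5, 5))
  g <- load_dose(f)
  expect_equal(g$values[1, 1, 1], 5.0)        # 5000 x 1e-3 Gy
  expect_equal(g$spacing[3], 2.5)             # constant frame-offset diff
  expect_equal(dim(g$values), c(1L, 1L, 3L))

  f2 <- .mini_dose_file(file.path(dir, "bad.dcm"), stored = c(1L, 1L, 1L),
                        scaling = 1e-3, offsets = c(0, 2.5, 5.6))
  expect_error(load_dose(f2), "[Nn]on-uniform")

  f3 <- .mini_dose_file(file.path(dir, "noscale.dcm"), stored = c(1L, 1L),
                        scaling = 1, offsets = c(0, 2.5), drop_scaling = TRUE)
  expect_error(load_dose(f3), "DoseGridScaling")
})

test_that("phantom bundles round-trip through the DICOM layer", {
  spec <- ph_spec(r0 = 8, sp = 1)
  b <- make_sphere_phantom(spec)
  dir <- withr::local_tempdir()
  paths <- write_dicom_bundle(b, dir)

  g <- load_dose(paths["dose"])
  quantum <- max(b$dose$values) / 60000
  expect_lt(max(abs(g$values - b$dose$values)), quantum)  # one scaling quantum
  expect_equal(g$spacing, b$dose$spacing)
  expect_equal(g$origin, b$dose$origin)

  rois <- load_structures(paths["struct"], g)
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$name, "Target")
  expect_length(rois[[1]]$contours, length(b$roi$contours))
  for (i in seq_along(b$roi$contours)) {
    expect_lt(max(abs(rois[[1]]$contours[[i]]$xy - b$roi$contours[[i]]$xy)),
              1e-6)
    expect_equal(rois[[1]]$contours[[i]]$z, b$roi$contours[[i]]$z,
                 tolerance = 1e-9)
  }
  expect_false(attr(rois[[1]], "out_of_grid"))

  p <- load_plan(paths["plan"])
  expect_equal(p$rx_gy, spec$d0_gy)
  expect_equal(p$n_fractions, 1L)
})

test_that("structure loader flags degenerate and out-of-grid contours", {
  dir <- withr::local_tempdir()
  # one healthy square ROI, one ROI with an empty contour sequence, and a
  # contour with 2 vertices that must be rejected
  sq <- lapply(0:4, function(k) {
    pts <- as.numeric(t(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), k * 2)))
    list("3006,0042" = list(vr = "CS", value = "CLOSED_PLANAR"),
         "3006,0046" = list(vr = "IS", value = 4L),
         "3006,0050" = list(vr = "DS", value = pts))
  })
  degen <- list(list(
    "3006,0042" = list(vr = "CS", value = "CLOSED_PLANAR"),
    "3006,0046" = list(vr = "IS", value = 2L),
    "3006,0050" = list(vr = "DS", value = c(0, 0, 0, 1, 1, 0))))
  el <- list(
    "0008,0016" = list(vr = "UI", value = rtdgc:::UID_RT_STRUCT),
    "3006,0020" = list(vr = "SQ", value = list(
      list("3006,0022" = list(vr = "IS", value = 1L),
           "3006,0026" = list(vr = "LO", value = "Box")),
      list("3006,0022" = list(vr = "IS", value = 2L),
           "3006,0026" = list(vr = "LO", value = "Empty")),
      list("3006,0022" = list(vr = "IS", value = 3L),
           "3006,0026" = list(vr = "LO", value = "Degenerate")))),
    "3006,0039" = list(vr = "SQ", value = list(
      list("3006,0084" = list(vr = "IS", value = 1L),
           "3006,0040" = list(vr = "SQ", value = sq)),
      list("3006,0084" = list(vr = "IS", value = 2L),
           "3006,0040" = list(vr = "SQ", value = list())),
      list("3006,0084" = list(vr = "IS", value = 3L),
           "3006,0040" = list(vr = "SQ", value = degen))))
  )
  f <- file.path(dir, "ss.dcm")
  dcm_write(el, f, rtdgc:::UID_RT_STRUCT, "1.2.3.6")

  grid <- uniform_grid(1, n = 12, sp = 1)
  expect_warning(rois <- load_structures(f, grid), "fewer than 3 vertices")
  expect_length(rois, 3L)
  expect_length(rois[[1]]$contours, 5L)       # one square per slice
  expect_length(rois[[2]]$contours, 0L)       # empty, flagged not dropped
  expect_true(isTRUE(attr(rois[[2]], "empty")))
  expect_true(attr(rois[[2]], "out_of_grid"))
  expect_length(rois[[3]]$contours, 0L)
  expect_false(attr(rois[[1]], "out_of_grid"))
})

test_that("prescription resolution follows precedence and the 5/6 rule", {
  g <- uniform_grid(24, n = 4)
  est <- resolve_prescription(NULL, g)
  expect_equal(est$rx_gy, 20)                 # 5/6 x 24, exact
  expect_equal(est$source, "estimated")
  # 5/6 of Dmax sits at about the 83% isodose level
  expect_equal(est$rx_gy / max(g$values), 5 / 6)
  expect_equal(round(100 * est$rx_gy / max(g$values)), 83)

  plan <- list(rx_gy = 75.6, n_fractions = 42L)
  from_plan <- resolve_prescription(plan, g)
  expect_equal(from_plan$rx_gy, 75.6)
  expect_equal(from_plan$n_fractions, 42L)
  expect_equal(from_plan$source, "plan_file")

  user <- resolve_prescription(plan, g, user_rx = 18)
  expect_equal(user$rx_gy, 18)
  expect_equal(user$source, "user")

  # idempotent / precedence-stable
  expect_identical(resolve_prescription(plan, g), from_plan)
  expect_identical(resolve_prescription(NULL, g), est)

  # plan without a target prescription falls back with a warning
  expect_warning(fb <- resolve_prescription(list(rx_gy = NULL), g),
                 "falling back")
  expect_equal(fb$source, "estimated")
})
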