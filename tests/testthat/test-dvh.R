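# Structure masks, DVH curves, clinical metrics, conformity/gradient
# indices.

test_that("structure masks use centre-in-polygon with even-odd parity", {
  # a square spanning exactly 10 x 10 voxel centres includes all of them
  g <- uniform_grid(10, n = 12, sp = 1)       # centres at 0..11 mm
  roi <- square_roi(9, planes = 3, cx = 4.5, cy = 4.5)  # edges on centres
  m <- structure_mask(g, roi)
  expect_equal(sum(m), 100L)
  expect_equal(sum(m[, , 4]), 100L)           # plane z=3 -> slice 4

  # annulus: the inner polygon carves a hole
  ann <- structure(list(name = "Ann", number = 1L, contours = list(
    list(z = 3, xy = cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5))),
    list(z = 3, xy = cbind(c(2.5, 6.5, 6.5, 2.5), c(2.5, 2.5, 6.5, 6.5))))),
    class = "roi")
  m2 <- structure_mask(g, ann)
  expect_equal(sum(m2), 100L - 16L)

  # no overlapping plane -> empty mask with warning
  far <- square_roi(4, planes = 100)
  expect_warning(m3 <- structure_mask(g, far), "overlap")
  expect_equal(sum(m3), 0L)
})

test_that("sphere ROI voxelization agrees with analytic membership", {
  spec <- ph_spec(r0 = 10, sp = 0.5)
  b <- make_sphere_phantom(spec)
  m <- structure_mask(b$dose, b$roi)
  truth <- b$dose$values >= spec$d0_gy        # dose >= d0 iff r <= r0
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gte(dice, 0.98)
})

test_that("cumulative DVHs have the step-function structure", {
  g <- uniform_grid(10, n = 6)
  roi_all <- array(TRUE, dim = dim(g$values))
  dvh <- compute_dvh(g, roi_all)
  expect_equal(dvh$volume_pct[1], 100)        # everything at dose 0
  expect_equal(dvh$volume_mm3[1], 216)
  i <- which(dvh$dose_gy <= 9.99)
  expect_true(all(dvh$volume_pct[i] == 100))
  expect_equal(dvh$volume_pct[length(dvh$volume_pct)], 0)
  expect_true(all(diff(dvh$volume_mm3) <= 0))

  # two-level structure: half at 5 Gy, half at 10 Gy
  v <- array(5, dim = c(4, 4, 4)); v[1:2, , ] <- 10
  g2 <- dose_grid(v, spacing = c(1, 1, 1))
  dvh2 <- compute_dvh(g2, array(TRUE, dim = dim(v)))
  expect_equal(as.numeric(volume_at_dose(dvh2, 4)$pct), 100)
  expect_equal(as.numeric(volume_at_dose(dvh2, 7.5)$pct), 50)
  expect_equal(dvh2$volume_pct[dvh2$dose_gy == 10], 50)

  expect_error(compute_dvh(g, array(FALSE, dim = dim(g$values))), "empty")
})

test_that("Dx and Vx interpolate the cumulative curve", {
  g <- uniform_grid(10, n = 6)
  dvh <- compute_dvh(g, array(TRUE, dim = dim(g$values)))
  expect_equal(as.numeric(dose_at_volume(dvh, 95)), 10, tolerance = 0.002)
  expect_equal(as.numeric(volume_at_dose(dvh, 5)$pct), 100)
  expect_equal(as.numeric(volume_at_dose(dvh, 15)$pct), 0)
  expect_equal(volume_at_dose(dvh, 0)$mm3, dvh$total_mm3)

  # linear ramp 0..20 Gy: D50 and V10 sit at the midpoint
  n <- 20
  ramp <- dose_grid(array(rep(seq(0.5, 19.5, length.out = n), each = n * n),
                          dim = c(n, n, n)), spacing = c(1, 1, 1))
  dvh_r <- compute_dvh(ramp, array(TRUE, dim = c(n, n, n)))
  expect_equal(as.numeric(dose_at_volume(dvh_r, 50)), 10, tolerance = 0.06)
  expect_equal(as.numeric(volume_at_dose(dvh_r, 10)$pct), 50, tolerance = 0.5)

  # two-level boundary case resolved by interpolation: D50 = 10 Gy
  v <- array(5, dim = c(4, 4, 4)); v[1:2, , ] <- 10
  dvh2 <- compute_dvh(dose_grid(v, spacing = c(1, 1, 1)),
                      array(TRUE, dim = dim(v)))
  expect_equal(as.numeric(dose_at_volume(dvh2, 50)), 10, tolerance = 0.002)

  # Dx/Vx duality across the curve interior
  for (x in c(10, 25, 50, 75, 90)) {
    d <- as.numeric(dose_at_volume(dvh_r, x))
    expect_equal(as.numeric(volume_at_dose(dvh_r, d)$pct), x,
                 tolerance = 0.6)
  }
})

test_that("summary statistics use the trapezoidal mean and Dx surrogates", {
  g <- uniform_grid(10, n = 6)
  s <- dvh_summary(compute_dvh(g, array(TRUE, dim = dim(g$values))))
  expect_equal(s$mean_gy, 10, tolerance = 0.002)
  expect_equal(s$max_gy, 10, tolerance = 0.002)   # D2 surrogate
  expect_equal(s$min_gy, 10, tolerance = 0.002)   # D98 surrogate

  v <- array(5, dim = c(4, 4, 4)); v[1:2, , ] <- 10
  s2 <- dvh_summary(compute_dvh(dose_grid(v, spacing = c(1, 1, 1)),
                                array(TRUE, dim = dim(v))))
  expect_equal(s2$mean_gy, 7.5, tolerance = 0.01)
})

test_that("DVH volume at zero dose matches the shoelace structure volume", {
  spec <- ph_spec(r0 = 10, sp = 0.5)
  b <- make_sphere_phantom(spec)
  dvh <- compute_dvh(b$dose, b$roi)
  sv <- contour_volume_shoelace(b$roi, thickness = 0.5)
  expect_equal(dvh$volume_mm3[1], sv, tolerance = 0.02)
})

test_that("Paddick CI matches its closed-form cases", {
  a <- array(FALSE, dim = c(10, 10, 10)); a[3:6, 3:6, 3:6] <- TRUE
  expect_equal(paddick_ci(a, a, c(1, 1, 1)), 1.0)  # perfect conformity

  piv <- array(FALSE, dim = c(10, 10, 10)); piv[3:6, 3:6, 3:10] <- TRUE
  expect_equal(paddick_ci(a, piv, c(1, 1, 1)), 0.5)  # TV inside 2x PIV

  b <- array(FALSE, dim = c(10, 10, 10)); b[8:9, 8:9, 1:2] <- TRUE
  expect_equal(paddick_ci(a, b, c(1, 1, 1)), 0)      # disjoint

  expect_error(paddick_ci(a, array(FALSE, dim = dim(a)), c(1, 1, 1)),
               "empty")
})

test_that("gradient index follows the spherical cube law", {
  for (r0 in c(10, 20)) {
    spec <- ph_spec(r0 = r0, sp = 0.5)
    b <- make_sphere_phantom(spec)
    tr <- analytic_truth(spec)
    gi <- gradient_index(b$dose, spec$d0_gy)
    expect_equal(gi, (1 + tr$fall_off_mm / r0)^3, tolerance = 0.05)
    expect_gte(gi, 1)
    r <- r50(b$dose, spec$d0_gy,
             contour_volume_shoelace(b$roi, thickness = 0.5))
    expect_equal(r, tr$v_of_d(0.5 * spec$d0_gy) / tr$v_of_d(spec$d0_gy),
                 tolerance = 0.05)
  }

  # degenerate step profile: prescription and half-prescription isodoses
  # coincide, so GI = 1
  v <- array(0, dim = c(10, 10, 10)); v[4:7, 4:7, 4:7] <- 13
  expect_equal(gradient_index(dose_grid(v, spacing = c(1, 1, 1)), 13), 1)
})
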