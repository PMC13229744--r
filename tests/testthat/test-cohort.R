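# Cohort statistics: correlations, paired reproducibility, subgroup
# summaries, and batch analysis.

test_that("correlation coefficients and p-values behave canonically", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.5, 6.1, 7.9, 9.0)
  r <- correlate(x, 2 * x + 1)
  expect_equal(r$pearson_r, 1.0)
  expect_lt(r$pearson_p, 1e-6)
  expect_equal(r$spearman_rho, 1.0)

  # monotone nonlinear: rank correlation saturates, Pearson does not
  r2 <- correlate(x, x^3)
  expect_equal(r2$spearman_rho, 1.0)
  expect_lt(r2$pearson_r, 1.0)

  expect_warning(rc <- correlate(rep(2, 5), 1:5), "constant")
  expect_true(is.na(rc$pearson_r))

  # null simulation: independent series give mean r near zero
  set.seed(42)
  rs <- replicate(300, correlate(rnorm(100), rnorm(100))$pearson_r)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("mean absolute percentage difference is symmetric and scale-free", {
  expect_equal(mapd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mapd(10, 11), 100 * 1 / 10.5)  # ~9.52%
  a <- c(5, 8, 13, 21); b <- c(5.2, 7.7, 13.4, 20.1)
  expect_equal(mapd(a, b), mapd(b, a))
  expect_equal(mapd(3 * a, 3 * b), mapd(a, b))
  expect_warning(z <- mapd(c(0, 10), c(0, 11)), "zero mean")
  expect_equal(z, 100 * 1 / 10.5)

  # +-1% multiplicative perturbation recovers ~1%
  set.seed(7)
  base <- runif(1000, 1, 100)
  pert <- base * (1 + sample(c(-0.01, 0.01), 1000, replace = TRUE))
  expect_equal(mapd(base, pert), 1.0, tolerance = 0.02)
})

test_that("subgroup summaries use upper-inclusive volume bands", {
  rec <- data.frame(tv_cc = c(0.5, 0.9, 1.0, 2.2, 3.0, 5.1),
                    ddgi = c(0.2, 0.25, 0.33, 0.35, 0.44, 0.42))
  s <- subgroup_summary(rec, volume_breaks = c(1, 3), metrics = "ddgi")
  expect_equal(unique(s$group), c("<1", "1-3", ">=3"))
  expect_equal(s$n, c(2L, 2L, 2L))            # 1.0 cc joins the 1-3 band
  expect_equal(s$mean[s$group == "<1"], 0.225)
  expect_equal(s$mean[s$group == ">=3"], 0.43)  # 3.0 cc joins >=3

  # single band contains everything: group mean is the overall mean
  s1 <- subgroup_summary(rec, volume_breaks = 100, metrics = "ddgi")
  expect_equal(s1$mean[1], mean(rec$ddgi))
  expect_equal(s1$n[2], 0L)                   # empty upper band reported
})

test_that("a cohort of phantoms reproduces the size-(in)dependence of the metrics", {
  dir <- withr::local_tempdir()
  # fixed fall-off slope, growing target: dDGI stays a physical distance
  # while the volume-ratio GI shrinks with target size
  radii <- c(8, 11, 14)
  rows <- lapply(seq_along(radii), function(i) {
    spec <- ph_spec(r0 = radii[i], sp = 1)
    paths <- write_dicom_bundle(make_sphere_phantom(spec),
                                file.path(dir, paste0("case", i)))
    data.frame(case_id = paste0("case", i), dose = paths["dose"],
               struct = paths["struct"], plan = paths["plan"])
  })
  manifest <- do.call(rbind, rows)
  records <- cohort_analyze(manifest, step = 2 * 13 / 6, step_unit = "Gy")
  expect_equal(nrow(records), 3L)
  expect_true(all(diff(records$gi) < 0))       # GI falls with r0
  spread <- diff(range(records$ddgi_at_rx_mm)) / mean(records$ddgi_at_rx_mm)
  expect_lt(spread, 0.10)                      # dDGI nearly constant
  expect_true(all(records$grade == "Ideal"))

  # failing case is skipped with a warning, not fatal
  bad <- rbind(manifest,
               data.frame(case_id = "broken", dose = "missing.dcm",
                          struct = "missing.dcm", plan = ""))
  # the unreadable file raises its own warning before the case-level one
  warns <- capture_warnings(rec2 <- cohort_analyze(bad, step = 2 * 13 / 6,
                                                   step_unit = "Gy"))
  expect_true(any(grepl("broken", warns)))
  expect_equal(nrow(rec2), 3L)
  expect_equal(attr(rec2, "failed"), "broken")

  expect_error(cohort_analyze(manifest[0, ]), "empty")
})

test_that("volume-dependent gradients order the subgroup means", {
  dir <- withr::local_tempdir()
  # larger targets get shallower fall-off (slope scaled by 10/r0), the
  # typical clinical pattern behind the volume bands
  radii <- c(5, 6, 8, 8.5, 9.5, 10.5)   # ~0.5/0.9/2.1/2.6/3.6/4.8 cc
  rows <- lapply(seq_along(radii), function(i) {
    spec <- phantom_spec(r0_mm = radii[i], d0_gy = 13,
                         g_gy_per_mm = (13 / 6) * 10 / radii[i],
                         spacing_mm = 1, center_mm = ph_off(1))
    paths <- write_dicom_bundle(make_sphere_phantom(spec),
                                file.path(dir, paste0("v", i)))
    data.frame(case_id = paste0("v", i), dose = paths["dose"],
               struct = paths["struct"], plan = paths["plan"])
  })
  records <- cohort_analyze(do.call(rbind, rows), step = 5)
  s <- subgroup_summary(records, volume_breaks = c(1, 3),
                        metrics = "ddgi_at_rx_mm")
  expect_equal(s$n, c(2L, 2L, 2L))
  expect_true(all(diff(s$mean) > 0))           # strictly increasing bands
})
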