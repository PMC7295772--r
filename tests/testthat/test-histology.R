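test_that("atresia prevalence is the fraction of fish with alpha atresia", {
  tbl <- tibble::tibble(n_alpha = c(rep(0, 66), c(2, 1, 3, 1, 1, 4)))
  p <- atresia_prevalence(tbl)
  expect_equal(p$n_fish, 72)
  expect_equal(p$n_atretic, 6)
  expect_equal(p$percent, 8.3)

  expect_equal(atresia_prevalence(tibble::tibble(n_alpha = rep(0, 10)))$percent, 0)
  expect_equal(atresia_prevalence(tibble::tibble(n_alpha = 1:5))$percent, 100)
  expect_error(atresia_prevalence(tibble::tibble(n_alpha = numeric(0))), "no fish")
})

test_that("atresia intensity is the atretic fraction of scored oocytes", {
  expect_equal(atresia_intensity(0, 50), 0)
  expect_equal(atresia_intensity(25, 25), 0.5)
  expect_equal(atresia_intensity(3, 47), 0.06)
  expect_error(atresia_intensity(0, 0), "undefined")
})

test_that("the Weibel estimator reproduces its closed form", {
  # single field: 26 of 256 points -> Vv
  one <- weibel_pof_number(26, 3, ow_g = 50)
  expect_equal(one$vv, 26 / 256, tolerance = 1e-12)

  # na = 10 / mm^2, vv = 0.1 -> nv = (1/1.38) * 10^1.5 / sqrt(0.1)
  m <- weibel_pof_number(
    points_on_pof = rep(25.6, 10), pof_profiles = rep(60, 10), ow_g = 104.64
  )
  expect_equal(m$vv, 0.1)
  expect_equal(m$na_per_mm2, 10)
  expect_equal(m$nv_per_mm3, 10^1.5 / sqrt(0.1) / 1.38, tolerance = 1e-12)
  expect_equal(m$nv_per_mm3, 72.46, tolerance = 5e-4)
  expect_equal(m$ovary_volume_cm3, 100)
  expect_equal(m$f_pof, m$nv_per_mm3 * 1e5)

  # homogeneity: doubling Na multiplies Nv by 2^(3/2) at fixed Vv
  m2 <- weibel_pof_number(rep(25.6, 10), rep(120, 10), ow_g = 104.64)
  expect_equal(m2$nv_per_mm3 / m$nv_per_mm3, 2^1.5, tolerance = 1e-12)

  expect_error(weibel_pof_number(0, 3, ow_g = 10), "inconsistent")
  zero <- weibel_pof_number(rep(0, 10), rep(0, 10), ow_g = 10)
  expect_equal(zero$f_pof, 0)
})

test_that("the estimator recovers sphere number density within 15%", {
  set.seed(2024)
  nv_true <- 2.5 # per mm^3
  r_mm <- 0.18
  est <- replicate(60, {
    cts <- section_sphere_counts(nv_true, r_mm)
    weibel_pof_number(cts$points_on_pof, cts$pof_profiles, ow_g = 10,
                      grid_points = cts$grid_points,
                      field_area_mm2 = cts$field_area_mm2)$nv_per_mm3
  })
  expect_lt(abs(mean(est) - nv_true) / nv_true, 0.15)
})

test_that("POF size metrics apply strict thresholds and fecundity ratios", {
  m <- pof_size_metrics(c(0.05, 0.11, 0.09), bw_g = 10000, ow_g = 500,
                        f_pof = 1000)
  expect_equal(m$pof_xsa_mm2, 0.11)
  expect_true(m$recent_spawner_010)
  expect_false(m$recent_spawner_011) # 0.11 is not > 0.11
  expect_equal(m$rf_pof, 0.1)
  expect_equal(m$rf_o_pof, 1000 / 9500)
  expect_gt(m$rf_o_pof, m$rf_pof)

  none <- pof_size_metrics(numeric(0), bw_g = 5000, ow_g = 100, f_pof = 0)
  expect_true(is.na(none$pof_xsa_mm2))
  expect_false(none$recent_spawner_010)
  expect_false(none$recent_spawner_011)

  expect_error(pof_size_metrics(0.1, bw_g = 100, ow_g = 200, f_pof = 1),
               "exceed")
})

test_that("per-ORC POF summaries aggregate the expected columns", {
  set.seed(5)
  tbl <- tibble::tibble(
    orc = rep(1:4, each = 5),
    pof_xsa_mm2 = runif(20, 0.02, 0.15),
    rf_pof = runif(20, 0, 0.3),
    recent_spawner_010 = runif(20) < 0.3,
    recent_spawner_011 = runif(20) < 0.2
  )
  s <- summarise_pof_by_orc(tbl)
  expect_equal(nrow(s), 4)
  expect_equal(s$n, rep(5L, 4))
  expect_equal(s$median_rf_pof,
               tapply(tbl$rf_pof, tbl$orc, median), ignore_attr = TRUE)
})
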