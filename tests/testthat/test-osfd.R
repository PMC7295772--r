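test_that("histogram bins are half-open and counts are conserved", {
  o <- build_osfd(c(110, 115, 130), bin_width_um = 20)
  expect_equal(o$histogram$bin_start_um[1:2], c(100, 120))
  expect_equal(o$histogram$count[1:2], c(2, 1))
  # boundary value 120 falls in [120, 140)
  o2 <- build_osfd(c(110, 120), bin_width_um = 20)
  expect_equal(o2$histogram$count[1:2], c(1, 1))

  set.seed(8)
  d <- runif(1000, 100, 1500)
  expect_equal(sum(build_osfd(d)$histogram$count), 1000)
  expect_identical(build_osfd(d)$histogram, build_osfd(d)$histogram)
  expect_error(build_osfd(numeric(0)), "zero diameters")
})

test_that("the smoothed density is normalized and finds the modes", {
  set.seed(10)
  tight <- rnorm(500, 500, 10)
  o <- smooth_osfd(build_osfd(tight))
  expect_equal(sum((o$density$density[-1] + o$density$density[-1501]) / 2), 1,
               tolerance = 1e-6)
  expect_lt(abs(o$density$diameter_um[which.max(o$density$density)] - 500), 15)

  mix <- c(rnorm(800, 300, 30), rnorm(1200, 800, 40))
  om <- smooth_osfd(build_osfd(mix))
  ann <- annotate_cohorts(om)
  modes <- ann$mode_diameters_um[[1]]
  expect_equal(length(modes), 2)
  expect_lt(abs(modes[1] - 300), 25)
  expect_lt(abs(modes[2] - 800), 25)

  expect_error(smooth_osfd(build_osfd(c(200, 300, 400, 500))), "at least 5")
})

test_that("leading cohort mean matches a brute-force top-k oracle", {
  expect_equal(leading_cohort_mean(c(100, 200, 300, 400, 500, 600, 700)), 500)
  x <- c(150, 220, 390, 410, 515)
  expect_equal(leading_cohort_mean(x, k = 5), mean(x))
  expect_error(leading_cohort_mean(c(1, 2, 3)), "at least k")

  set.seed(4)
  for (i in 1:20) {
    x <- sample(round(runif(30, 100, 1000), -1), 25) # duplicates likely
    oracle <- mean(rev(sort(x))[1:5])
    expect_equal(leading_cohort_mean(x, 5), oracle)
  }
})

test_that("cohort annotation reproduces the qualitative OSFD phenotypes", {
  set.seed(12)
  single <- annotate_cohorts(build_osfd(rnorm(800, 600, 50)))
  expect_equal(single$n_cohorts_dev, 1)
  expect_false(single$bimodal_vo)
  expect_false(single$budding_peak)
  expect_false(single$long_tail)

  # two developing cohorts with a deep valley; upper mode past hydration onset
  two <- c(rnorm(600, 500, 45), rnorm(500, 900, 45))
  ann2 <- annotate_cohorts(build_osfd(two))
  expect_gte(ann2$n_cohorts_dev, 2)
  expect_true(ann2$bimodal_vo)
  expect_true(ann2$budding_peak)

  # long tail: 8% of oocytes scattered above the 800 um cohort
  tail_fish <- c(rnorm(900, 800, 40), runif(80, 900, 1200))
  ann3 <- annotate_cohorts(build_osfd(tail_fish))
  expect_true(ann3$long_tail)
})

test_that("mixture mode count is recovered when components are separable", {
  set.seed(99)
  hits <- 0
  for (i in 1:100) {
    sds <- runif(2, 25, 80) # realistic cohort spreads
    mu1 <- runif(1, 300, 600)
    mu2 <- mu1 + runif(1, 4, 6) * max(sds) # separability condition
    x <- c(rnorm(900, mu1, sds[1]), rnorm(900, mu2, sds[2]))
    x <- x[x >= 110 & x <= 1600]
    ann <- annotate_cohorts(smooth_osfd(build_osfd(x)))
    if (ann$n_modes == 2) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("hiatus limits are placed in a clean gap and flag occupied gaps", {
  set.seed(21)
  clean <- c(rnorm(500, 150, 25), rnorm(300, 700, 50))
  h <- hiatus_limits(build_osfd(clean))
  expect_true(h$hiatus_present)
  expect_false(h$ambiguous)
  expect_gt(h$lower_um, 150)
  expect_lt(h$upper_um, 700)
  expect_lt(h$lower_um, h$upper_um)

  contaminated <- c(clean, runif(90, 250, 500))
  hc <- hiatus_limits(build_osfd(contaminated))
  expect_true(hc$ambiguous)

  pvo_only <- hiatus_limits(build_osfd(rnorm(400, 160, 30)))
  expect_false(pvo_only$hiatus_present)
  expect_true(is.na(pvo_only$lower_um))
})

test_that("hiatus width grows as the developing pool is spawned down", {
  # deterministic quantile cohorts isolate the depletion response from
  # sampling noise: a fixed PVO pool against a shrinking developing pool
  pvo <- qnorm(ppoints(500), 160, 30)
  widths <- sapply(c(600, 450, 300, 150, 60), function(n_dev) {
    dev <- qnorm(ppoints(n_dev), 700, 55)
    h <- hiatus_limits(build_osfd(c(pvo, dev)))
    expect_true(h$hiatus_present)
    expect_false(h$ambiguous)
    h$width_um
  })
  expect_true(all(diff(widths) >= 0))
})

test_that("gap contamination produces roughly the expected ambiguity rate", {
  # 15% of fish get an occupied hiatus; the flag should fire for about them
  set.seed(77)
  n_amb <- 0
  for (i in 1:40) {
    contaminated <- i <= 6
    sim <- simulate_cohort(
      spec_for_or(0.8, gap_contamination = if (contaminated) 0.12 else 0),
      seed = 500 + i
    )
    h <- hiatus_limits(build_osfd(sim$diameters$diameter_um))
    n_amb <- n_amb + isTRUE(h$ambiguous)
  }
  expect_gte(n_amb, 4)
  expect_lte(n_amb, 10)
})
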