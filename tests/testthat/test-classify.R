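test_that("oocyte ratio counts the windows and excludes hydrated eggs", {
  set.seed(2)
  d <- c(runif(300, 100, 249.9), runif(300, 250, 1200))
  r <- oocyte_ratio(d)
  expect_equal(r$n_pvo, 300)
  expect_equal(r$n_dev, 300)
  expect_equal(r$or_value, 1)
  expect_false(r$zero_denominator_used)

  d2 <- c(runif(450, 100, 249.9), runif(30, 250, 1200), runif(40, 1201, 1600))
  r2 <- oocyte_ratio(d2)
  expect_equal(r2$n_hydrated, 40)
  expect_equal(r2$or_value, 15)

  # window boundary semantics: 250 is developing, 1200 is developing
  r3 <- oocyte_ratio(c(249.999, 250, 1200, 1200.001))
  expect_equal(r3$n_pvo, 1)
  expect_equal(r3$n_dev, 2)
  expect_equal(r3$n_hydrated, 1)
})

test_that("a zero developing count uses the substitute denominator", {
  set.seed(3)
  r <- oocyte_ratio(runif(300, 100, 249.9))
  expect_equal(r$or_value, 300)
  expect_true(r$zero_denominator_used)
  expect_error(oocyte_ratio(c(1300, 1400)), "no countable")
})

test_that("ORC boundaries follow the category table", {
  expect_equal(classify_orc(c(0.2, 1.0, 1.000001, 2.5, 3, 3.01, 15, 15.000001, 40)),
               c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(classify_orc(0), "positive")
  expect_error(classify_orc(-1), "positive")
})

test_that("OR is scale invariant and strictly decreasing in the developing count", {
  set.seed(6)
  pvo <- runif(120, 100, 249)
  dev <- runif(40, 300, 900)
  r1 <- oocyte_ratio(c(pvo, dev))
  r2 <- oocyte_ratio(c(rep(pvo, 3), rep(dev, 3)))
  expect_equal(r1$or_value, r2$or_value)
  expect_equal(classify_orc(r1$or_value), classify_orc(r2$or_value))

  ors <- sapply(c(40, 30, 20, 10, 5, 1), function(k) {
    oocyte_ratio(c(pvo, dev[seq_len(k)]))$or_value
  })
  expect_true(all(diff(ors) > 0))
  expect_true(all(diff(classify_orc(ors)) >= 0))
})

test_that("multinomial sampling noise rarely changes the assigned category", {
  targets <- c(0.5, 2, 8, 30)
  correct <- 0
  total <- 0
  for (s in 1:200) {
    set.seed(s)
    for (k in seq_along(targets)) {
      p_dev <- 1 / (1 + targets[k])
      counts <- rmultinom(1, 400, c(1 - p_dev, p_dev))[, 1]
      d <- c(runif(counts[1], 100, 249.9), runif(counts[2], 250, 1200))
      orc <- classify_orc(oocyte_ratio(d)$or_value)
      correct <- correct + (orc == k)
      total <- total + 1
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("PVO fecundity is the OW x OR x OPD product", {
  expect_equal(pvo_fecundity(2, ow_g = 500, opd_vo_per_g = 1000)$f_pvo, 1e6)
  expect_equal(pvo_fecundity(1, ow_g = 321, opd_vo_per_g = 1)$f_pvo, 321)
  or15 <- oocyte_ratio(c(runif(450, 100, 249.9), runif(30, 250, 1200)))$or_value
  expect_equal(pvo_fecundity(or15, ow_g = 200, opd_vo_per_g = 500)$f_pvo, 1.5e6)
  # power-law calibration route
  pl <- pvo_fecundity(2, ow_g = 100, opd_alpha = 2e9, opd_gamma = -2,
                      mean_vo_um = 800)
  expect_equal(pl$opd_vo_per_g, 2e9 * 800^-2)
  expect_error(pvo_fecundity(2, ow_g = 100), "calibration")
})

test_that("classify_fish processes a long oocyte table per fish", {
  set.seed(9)
  tbl <- dplyr::bind_rows(
    tibble::tibble(fish_id = "a", diameter_um = c(runif(100, 100, 249), runif(100, 250, 1200))),
    tibble::tibble(fish_id = "b", diameter_um = runif(80, 100, 249))
  )
  out <- classify_fish(tbl)
  expect_equal(out$orc[out$fish_id == "a"], 1L)
  expect_equal(out$orc[out$fish_id == "b"], 4L)
  expect_true(out$zero_denominator_used[out$fish_id == "b"])
})
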