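test_that("a blank micrograph yields no detections", {
  img <- matrix(255L, 200, 200)
  out <- detect_oocytes(img)
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 0)
})

test_that("malformed micrograph input is rejected", {
  expect_error(detect_oocytes(array(0, c(4, 4, 3))), "2-D")
  expect_error(detect_oocytes(matrix(-4, 5, 5)), "grey levels")
  expect_error(detect_oocytes(matrix(300, 5, 5)), "grey levels")
})

test_that("rendered ellipses are recovered within 2% of ground truth", {
  out <- render_micrograph(c(300, 500, 900), scene_spec(size_px = 700),
                           seed = 11)
  expect_equal(nrow(out$truth), 3)
  det <- detect_oocytes(out$pixels)
  expect_equal(nrow(det), 3)
  got <- sort(det$diameter_um)
  expect_true(all(abs(got - c(300, 500, 900)) / c(300, 500, 900) < 0.02))
})

test_that("a rendered circle has roundness close to 1", {
  out <- render_micrograph(400, scene_spec(size_px = 300,
                                           axis_ratio_range = c(1, 1)),
                           seed = 3)
  det <- detect_oocytes(out$pixels)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$roundness - 1), 0.02)
  expect_gt(det$ellipticity, 0.95)
})

test_that("border-touching objects are discarded", {
  img <- matrix(230L, 300, 300)
  img[1:40, 140:180] <- 30L     # touches top border
  img[140:180, 140:180] <- 30L  # interior
  det <- detect_oocytes(img)
  expect_equal(nrow(det), 1)
  expect_true(abs(det$centroid_row - 159.5) < 2)
})

test_that("acceptance thresholds follow the stated boundary semantics", {
  rec <- tibble::tibble(
    object_id = 1:6,
    diameter_um = c(90, 100, 1600, 1601, 500, 500),
    major_um = 1, minor_um = 1, area_um2 = 1,
    roundness = c(0.9, 0.8, 1.0, 0.9, 0.79, 0.9),
    ellipticity = c(0.95, 0.91, 0.95, 0.95, 0.95, 0.909),
    mean_grey = c(50, 110, 111, 50, 50, 50),
    centroid_row = 0, centroid_col = 0
  )
  out <- filter_oocytes(rec)
  expect_equal(out$passed_filter, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$rejection_reason,
               c("size", "none", "grey", "size", "roundness", "ellipticity"))
})

test_that("filtering is total, order-preserving and idempotent", {
  expect_equal(nrow(filter_oocytes(detect_oocytes(matrix(255L, 50, 50)))), 0)
  out <- render_micrograph(runif(20, 150, 900), seed = 5)
  det <- detect_oocytes(out$pixels)
  f1 <- filter_oocytes(det)
  f2 <- filter_oocytes(f1)
  expect_equal(f1$object_id, det$object_id)
  expect_equal(f2$passed_filter, f1$passed_filter)
  expect_equal(f2$rejection_reason, f1$rejection_reason)
})

test_that("pass/reject decisions are invariant to image resolution", {
  d <- c(150, 300, 550, 800, 1250)
  run_at <- function(res, size) {
    sc <- scene_spec(size_px = size, resolution_px_per_um = res, noise_sd = 0)
    out <- render_micrograph(d, sc, seed = 21)
    cfg <- detection_config(resolution_px_per_um = res)
    filter_oocytes(detect_oocytes(out$pixels, cfg), cfg)
  }
  a <- run_at(0.1803, 900)
  b <- run_at(0.3606, 1800)
  expect_equal(nrow(a), length(d))
  expect_equal(nrow(b), length(d))
  a <- a[order(a$diameter_um), ]
  b <- b[order(b$diameter_um), ]
  expect_equal(a$passed_filter, b$passed_filter)
  expect_true(all(abs(a$diameter_um - b$diameter_um) / a$diameter_um < 0.01))
})

test_that("per-fish pooling raises the sampling QC flags", {
  mk <- function(counts) {
    dplyr::bind_rows(lapply(seq_along(counts), function(i) {
      tibble::tibble(micrograph_id = i,
                     diameter_um = runif(counts[i], 150, 900),
                     passed_filter = TRUE)
    }))
  }
  ok <- merge_fish_detections(mk(c(80, 70, 60)))
  expect_equal(ok$n_oocytes, 210)
  expect_false(ok$low_count)
  expect_false(ok$few_micrographs)

  low <- merge_fish_detections(mk(c(50, 50, 50)))
  expect_true(low$low_count)
  expect_false(low$few_micrographs)

  few <- merge_fish_detections(mk(250))
  expect_false(few$low_count)
  expect_true(few$few_micrographs)
  expect_length(few$diameters[[1]], 250)
})
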