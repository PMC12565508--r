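test_that("scale factor is the physical/pixel ratio and rejects bad markers", {
  expect_equal(compute_scale_factor(marker_spec(30, 300)), 0.1)
  expect_equal(compute_scale_factor(marker_spec(30, 30)), 1.0)
  expect_equal(compute_scale_factor(marker_spec(25, 400)), 0.0625)
  expect_error(marker_spec(30, 0), "calibration error")
  expect_error(marker_spec(30, -5), "calibration error")
  expect_error(marker_spec(-1, 10), "positive")
  expect_error(marker_spec(30, 10, confidence = 1.5), "\\[0, 1\\]")
})

test_that("dimension conversion multiplies by alpha and round-trips exactly", {
  expect_equal(convert_dimension(650, 0.1), 65.0)
  expect_equal(convert_dimension(123.4, 1.0), 123.4)
  expect_error(convert_dimension(0, 0.1), "calibration error")
  expect_error(convert_dimension(100, 0), "calibration error")
  withr::with_seed(7, {
    for (i in 1:50) {
      d <- runif(1, 1, 500); a <- runif(1, 0.01, 2)
      expect_equal(convert_dimension(d / a, a), d, tolerance = 1e-12)
    }
  })
})

test_that("mask extraction matches the per-pixel bounding-box oracle", {
  sc <- make_scene()
  ex <- extract_dimensions_from_mask(sc, marker_physical_size_mm = 30)
  # isolate each component for the oracle
  marker_only <- sc; marker_only[40:260, ] <- 0L
  fruit_only <- sc; fruit_only[1:45, 1:45] <- 0L
  expect_identical(as.integer(oracle_bbox(marker_only)[["w"]]), 30L)
  expect_identical(ex$marker$pixel_size_px, 30)
  expect_identical(as.integer(ex$fruit_width_px),
                   as.integer(oracle_bbox(fruit_only)[["w"]]))
  expect_identical(as.integer(ex$fruit_height_px),
                   as.integer(oracle_bbox(fruit_only)[["h"]]))
  expect_length(ex$qc_flags, 0)
})

test_that("mask extraction errors and tie-breaks are honoured", {
  one <- matrix(0L, 60, 60); one[10:20, 10:20] <- 1L
  expect_error(extract_dimensions_from_mask(one), "extraction error")
  # two identical squares: ambiguous marker -> flagged, not an error
  two <- matrix(0L, 80, 80)
  two[5:24, 5:24] <- 1L
  two[40:59, 40:59] <- 1L
  ex <- extract_dimensions_from_mask(two)
  expect_true("low_marker_confidence" %in% ex$qc_flags)
  expect_identical(ex$marker$pixel_size_px, 20)
})

test_that("integer upscaling scales px dims but leaves mm dims unchanged", {
  sc <- make_scene()
  ex1 <- extract_dimensions_from_mask(sc, 30)
  a1 <- compute_scale_factor(ex1$marker)
  for (s in c(2L, 3L)) {
    big <- kronecker(sc, matrix(1L, s, s))
    ex2 <- extract_dimensions_from_mask(big, 30)
    expect_lte(abs(ex2$fruit_width_px - s * ex1$fruit_width_px), 1)
    expect_lte(abs(ex2$fruit_height_px - s * ex1$fruit_height_px), 1)
    a2 <- compute_scale_factor(ex2$marker)
    mm1 <- convert_dimension(ex1$fruit_width_px, a1)
    mm2 <- convert_dimension(ex2$fruit_width_px, a2)
    expect_lte(abs(mm1 - mm2), a2 * s) # quantisation allowance
  }
})

test_that("quality checks flag aspect ratio, marker confidence, occlusion", {
  ok <- fruit_dimensions(65, 62, 64, 60)
  expect_length(quality_check(ok, marker_confidence = 0.9), 0)
  bad <- fruit_dimensions(90, 40, 64, 60)
  expect_true("aspect_ratio_violation" %in% quality_check(bad))
  expect_true("low_marker_confidence" %in%
                quality_check(ok, marker_confidence = 0.2))
  touching <- quality_check(ok, fruit_bbox = c(xmin = 1, ymin = 20, xmax = 50,
                                               ymax = 70),
                            image_size = c(200, 200))
  expect_true("occlusion_suspect" %in% touching)
})

test_that("two-view assembly applies per-frame scale factors independently", {
  mk <- function(conf = 1) marker_spec(30, 300, conf) # alpha = 0.1
  top <- view_measurement("top", 650, 620, mk())
  side <- view_measurement("side", 640, 600, mk())
  d <- assemble_fruit_dimensions(top, side)
  expect_equal(c(d$w_top, d$h_top, d$w_side, d$h_side), c(65, 62, 64, 60))
  # side view at alpha = 0.2 doubles side mm for the same px
  side2 <- view_measurement("side", 640, 600, marker_spec(30, 150))
  d2 <- assemble_fruit_dimensions(top, side2)
  expect_equal(c(d2$w_side, d2$h_side), c(128, 120))
  # at alpha = 0.4 the side dims leave the 20-150 mm sanity range
  side4 <- view_measurement("side", 640, 600, marker_spec(30, 75))
  d4 <- assemble_fruit_dimensions(top, side4)
  expect_true("sanity_bounds_violation" %in% attr(d4, "qc_flags"))
  expect_error(assemble_fruit_dimensions(top, side4, strict = TRUE), "rejected")
})

test_that("dimension tables round-trip through CSV", {
  d1 <- fruit_dimensions(65, 62, 64, 60, "a")
  d2 <- fruit_dimensions(70, 68, 69, 66, "b")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dimension_table(list(d1, d2), path)
  back <- read_dimension_table(path)
  expect_equal(back$w_top_mm, c(65, 70))
  expect_equal(back$fruit_id, c("a", "b"))
  expect_error(read_dimension_table(write_dimension_table(
    data.frame(fruit_id = "x", w_top_mm = 1), path)), "missing columns")
})

test_that("mask PNGs round-trip through disk", {
  sc <- make_scene()
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(sc, path)
  back <- read_mask_png(path)
  expect_identical(back, sc)
  ex1 <- extract_dimensions_from_mask(sc, 30)
  ex2 <- extract_dimensions_from_mask(back, 30)
  expect_identical(ex1$fruit_width_px, ex2$fruit_width_px)
})
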