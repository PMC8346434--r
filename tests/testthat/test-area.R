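make_frame <- function(r, g, b, h = 4, w = 5) {
  fr <- array(0, dim = c(h, w, 3))
  fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
  fr
}

test_that("arithmetic intensity filters evaluate and clamp correctly", {
  expect_equal(apply_intensity_filter(make_frame(10, 50, 20), "diff_2G")[1, 1], 70)
  expect_equal(apply_intensity_filter(make_frame(100, 10, 50), "diff_2G")[1, 1], 0)
  expect_equal(apply_intensity_filter(make_frame(30, 60, 90), "mean_RGB")[1, 1], 60)
  expect_equal(apply_intensity_filter(make_frame(200, 255, 250), "diff_2B")[1, 1], 45)
  expect_equal(apply_intensity_filter(make_frame(7, 8, 9), "channel_B")[1, 1], 9)
  # HSB brightness of a pure grey is the grey level
  expect_equal(apply_intensity_filter(make_frame(128, 128, 128), "hsb_B")[1, 1], 128)
  expect_error(apply_intensity_filter(matrix(1, 3, 3), "diff_2G"), "RGB")
})

test_that("colour distances match their formulas and L1 dominates L2", {
  expect_equal(color_distance(c(5, 5, 5), c(5, 5, 5), "L1"), 0)
  expect_equal(color_distance(c(5, 5, 5), c(5, 5, 5), "L2"), 0)
  expect_equal(color_distance(c(0, 0, 0), c(1, 2, 3), "L1"), 6)
  expect_equal(color_distance(c(0, 0, 0), c(1, 2, 3), "L2"), sqrt(14))
  set.seed(4)
  px <- matrix(runif(3000, 0, 255), ncol = 3)
  rf <- runif(3, 0, 255)
  l1 <- color_distance(px, rf, "L1")
  l2 <- color_distance(px, rf, "L2")
  expect_true(all(l1 >= l2))
  # independent elementwise check
  expect_equal(l1, abs(px[, 1] - rf[1]) + abs(px[, 2] - rf[2]) + abs(px[, 3] - rf[3]))
  expect_equal(l2, sqrt((px[, 1] - rf[1])^2 + (px[, 2] - rf[2])^2 + (px[, 3] - rf[3])^2))
})

test_that("reference filter uses a strict min-distance threshold", {
  fr <- make_frame(100, 150, 100)
  f0 <- color_filter("ref_colors", 0, ref_colors = c(100, 150, 100))
  expect_false(any(apply_reference_filter(fr, f0)))
  f1 <- color_filter("ref_colors", 1, ref_colors = c(100, 150, 100))
  expect_true(all(apply_reference_filter(fr, f1)))
  expect_error(color_filter("ref_colors", 10), "reference colour")
})

test_that("reference filter equals the brute-force double loop", {
  set.seed(9)
  fr <- array(runif(6 * 8 * 3, 0, 255), dim = c(6, 8, 3))
  refs <- matrix(runif(9, 0, 255), ncol = 3)
  filt <- color_filter("ref_colors", 25, ref_colors = refs, metric = "L2")
  mask <- apply_reference_filter(fr, filt)
  for (i in 1:6) for (j in 1:8) {
    dmin <- Inf
    for (k in 1:3)
      dmin <- min(dmin, sqrt(sum((fr[i, j, ] - refs[k, ])^2)))
    expect_identical(mask[i, j], dmin < 25)
  }
})

test_that("per-ROI counting is strict and matches the pixel-loop oracle", {
  quad <- parallelogram(c(0, 0, 10, 0, 10, 10, 0, 10))
  rois <- roi_array(quad, c(0, 1), c(0, 1))
  expect_equal(unname(count_over_threshold(matrix(36, 10, 10), rois, 35)), 100L)
  expect_equal(unname(count_over_threshold(matrix(35, 10, 10), rois, 35)), 0L)

  set.seed(21)
  for (rep in 1:10) {
    vals <- matrix(runif(18 * 24, 0, 255), nrow = 18)
    thr <- runif(1, 0, 255)
    quad <- parallelogram(c(1.5, 1.2, 22.4, 1.8, 22.9, 16.6, 1.9, 16.1))
    rois <- roi_array(quad, c(0, runif(1, 0.2, 0.5), 1), c(0, runif(1, 0.3, 0.7), 1))
    expect_equal(unname(count_over_threshold(vals, rois, thr)),
                 unname(as.integer(brute_count(vals > thr, rois))))
  }
})

test_that("raising the intensity threshold never increases counts", {
  set.seed(2)
  vals <- matrix(runif(20 * 20, 0, 255), 20)
  rois <- roi_array(parallelogram(c(0, 0, 20, 0, 20, 20, 0, 20)),
                    c(0, 0.5, 1), c(0, 0.5, 1))
  prev <- count_over_threshold(vals, rois, 0)
  for (thr in seq(25, 250, by = 25)) {
    cur <- count_over_threshold(vals, rois, thr)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("measuring a constant stack yields constant, equal series", {
  res <- local_plate(rows = 2, cols = 3, n_frames = 5,
                     letters = rep("F", 6), sigma = 0)
  filt <- color_filter("diff_2G", 35)
  s <- measure_stack(res$frames, res$rois, filt, smooth_n = 3)
  # F-type consumes 3%: areas nearly constant; raw == avg == med when constant
  expect_equal(s$avg, s$raw, tolerance = 0.02)
  expect_equal(s$med, s$raw, tolerance = 0.02)
  s1 <- measure_stack(res$frames, res$rois, filt, smooth_n = 1)
  expect_identical(s1$avg, s1$raw)
  expect_identical(s1$med, s1$raw)
})

test_that("subsampling a stack retains ceiling(N/s) frames", {
  res <- local_plate(rows = 2, cols = 3, n_frames = 5)
  filt <- color_filter("diff_2G", 35)
  for (s in c(1, 2, 3, 5)) {
    ms <- measure_stack(res$frames, res$rois, filt, subsample_step = s, smooth_n = 1)
    expect_equal(nrow(ms$raw), ceiling(5 / s))
  }
})

test_that("the running median suppresses a single-frame occlusion", {
  # inject a dark blob over one cage in the middle frame by rendering a
  # stack with a forced fraction dip is not enough: paint the blob directly
  res <- local_plate(rows = 2, cols = 2, n_frames = 11, letters = rep("F", 4),
                     seed = 8)
  dir2 <- file.path(tempdir(), "blobbed")
  dir.create(dir2, showWarnings = FALSE)
  paths <- file.path(dir2, basename(res$frames))
  file.copy(res$frames, paths, overwrite = TRUE)
  img <- read_frame(paths[6])
  # cover the first cage's disk with a dark patch
  c1 <- res$rois$cells[[1]]$poly
  xm <- round(mean(c1[, 1])); ym <- round(mean(c1[, 2]))
  img[(ym - 15):(ym + 15), (xm - 15):(xm + 15), ] <- 40
  png::writePNG(img / 255, paths[6])

  filt <- color_filter("diff_2G", 35)
  s <- measure_stack(paths, res$rois, filt, smooth_n = 10)
  base <- median(s$raw[-6, 1])
  expect_lt(s$raw[6, 1], 0.5 * base)               # raw shows the dip
  expect_gt(min(s$med[, 1]), 0.9 * base)           # median removes it
})

test_that("area tables round-trip through CSV", {
  res <- local_plate(rows = 2, cols = 3, n_frames = 5)
  s <- measure_stack(res$frames, res$rois, color_filter("diff_2G", 35))
  prefix <- tempfile()
  export_area_table(s, prefix)
  df <- utils::read.csv(paste0(prefix, "_raw.csv"), check.names = FALSE)
  expect_equal(ncol(df), 6 + 1)      # one column per ROI plus time
  back <- read_area_table(prefix)
  expect_equal(back$raw, s$raw, ignore_attr = TRUE)
  expect_equal(back$med, s$med, ignore_attr = TRUE)
  expect_equal(back$time, s$time)
  expect_error(export_area_table(structure(list(time = numeric(0)),
                                           class = "area_series"), tempfile()),
               "empty")
})

test_that("unreadable frames are skipped with a warning, all-bad errors", {
  res <- local_plate(rows = 2, cols = 3, n_frames = 5)
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  filt <- color_filter("diff_2G", 35)
  expect_warning(
    s <- measure_stack(c(res$frames[1:2], bad, res$frames[4:5]), res$rois, filt,
                       smooth_n = 1),
    "unreadable")
  expect_equal(nrow(s$raw), 4)
  expect_error(suppressWarnings(measure_stack(c(bad, bad), res$rois, filt)),
               "no frame")
})
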