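make_cmap <- function(values, m = 3L, n = 3L, flat = NULL) {
  # bare correlation_map for detector unit tests
  structure(list(values = values,
                 flat = if (is.null(flat)) matrix(FALSE, nrow(values), ncol(values)) else flat,
                 scene_dims = c(nrow(values) + m - 1L, ncol(values) + n - 1L),
                 template_dims = c(m, n), template_id = "t"),
            class = "correlation_map")
}

test_that("thresholding above the maximum yields a valid empty set", {
  cm <- make_cmap(matrix(c(0.2, 0.5, 0.1, 0.4), 2, 2))
  ds <- detect(cm, 0.9)
  expect_s3_class(ds, "detection_set")
  expect_equal(nrow(ds), 0L)
  expect_error(detect(cm, -1), "threshold")
  expect_error(detect(cm, 1.2), "threshold")
})

test_that("a plateau groups to one detection but stays k raw detections", {
  v <- matrix(0, 5, 5)
  v[2, 2:4] <- 0.8          # 3 adjacent above-threshold pixels
  v[2, 3] <- 0.9            # unique peak
  cm <- make_cmap(v)
  grouped <- detect(cm, 0.7)
  raw <- detect(cm, 0.7, grouping = "raw")
  expect_equal(nrow(grouped), 1L)
  expect_equal(nrow(raw), 3L)
  expect_equal(grouped$anchor_row, 1L)   # 0-based peak position
  expect_equal(grouped$anchor_col, 2L)
  expect_equal(grouped$score, 0.9)
  # equal-score plateau: anchor tie-breaks to smallest (row, col)
  v2 <- matrix(0, 5, 5); v2[3, 2:3] <- 0.8; v2[2, 3] <- 0.8
  g2 <- detect(make_cmap(v2), 0.7)
  expect_equal(nrow(g2), 1L)
  expect_equal(c(g2$anchor_row, g2$anchor_col), c(1L, 2L))
})

test_that("exact planted template is recovered at threshold 0.99, zero noise", {
  tmpl <- make_template(41, c(12, 15))
  sc <- make_scene(42, size = c(128, 128), templates = list(tp = tmpl),
                   k_plants = 1)
  cm <- correlation_map(sc$scene, template_pattern(unclass(tmpl), "tp"))
  ds <- detect(cm, 0.99)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$anchor_row, sc$truth$row)
  expect_equal(ds$anchor_col, sc$truth$col)
  expect_equal(ds$height, 12L)
  expect_equal(ds$width, 15L)
})

test_that("detections carry grid labels of their box centres", {
  v <- matrix(0, 8, 8); v[1, 1] <- 0.95
  cm <- make_cmap(v, m = 3L, n = 3L)      # scene 10 x 10
  ds <- detect(cm, 0.9, grid = grid_config(1, 1))
  # box centre (1, 1) of a 10 x 10 scene: subcolumn A, subrow 1
  expect_equal(ds$grid_label, "1A1")
})

test_that("sweep counts are ordered by descending threshold and find the knee", {
  v <- matrix(0.9, 1, 1)
  sw <- sweep_thresholds(make_cmap(v), 0.5, 0.95, 0.05)
  expect_true(all(diff(sw$threshold) < 0))
  expect_equal(sw$n_detections[sw$threshold > 0.9], rep(0L, sum(sw$threshold > 0.9)))
  expect_equal(sw$n_detections[sw$threshold < 0.9], rep(1L, sum(sw$threshold < 0.9)))
})

test_that("grouped sweep counts never increase with threshold (20 random maps)", {
  for (seed in 0:19) {
    set.seed(seed)
    I <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    R <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
    cm <- correlation_map(I, template_pattern(R))
    sw <- sweep_thresholds(cm, 0.40, 0.95, 0.05)
    expect_true(all(diff(sw$n_detections) >= 0))  # descending thresholds
  }
})

test_that("select_threshold picks the last stable value before the jump", {
  sw <- data.frame(threshold = c(0.70, 0.69, 0.64),
                   n_detections = c(9L, 10L, 60L))
  expect_equal(select_threshold(sw, 6), 0.69)     # 60/10 >= 6
  # flat counts: midpoint with warning
  flat <- data.frame(threshold = seq(0.9, 0.5, by = -0.1),
                     n_detections = rep(4L, 5))
  expect_warning(mid <- select_threshold(flat), "midpoint")
  expect_equal(mid, 0.7)
  expect_error(select_threshold(data.frame(threshold = 0.5, n_detections = 0L)),
               "no detections")
})

test_that("efficiency reports the exact percent and errors on zero detected", {
  rep1 <- efficiency(18, 2)
  expect_equal(rep1$efficiency, 100 * 2 / 18)
  expect_equal(rep1$efficiency_pct, 11L)
  expect_equal(efficiency(7, 7)$efficiency, 100)
  expect_equal(efficiency(18, 0)$efficiency, 0)
  expect_error(efficiency(0, 0), "n_detected")
  expect_error(efficiency(10, 3, n_sampled = 2), "exceed")
})

test_that("run_detection writes a deterministic report and overlay", {
  t1 <- make_template(51, c(10, 12))
  t2 <- make_template(52, c(8, 9))
  sc <- make_scene(53, size = c(160, 160),
                   templates = list(a = t1, b = t2), k_plants = c(2, 3))
  d <- withr::local_tempdir()
  csv1 <- file.path(d, "r1.csv"); csv2 <- file.path(d, "r2.csv")
  ov <- file.path(d, "ov.png")
  res <- run_detection(sc$scene, list(a = t1, b = t2), threshold = 0.99,
                       report_csv = csv1, overlay_png = ov)
  run_detection(sc$scene, list(a = t1, b = t2), threshold = 0.99,
                report_csv = csv2)
  expect_equal(nrow(res), 5L)
  expect_identical(readBin(csv1, "raw", file.size(csv1)),
                   readBin(csv2, "raw", file.size(csv2)))
  got <- utils::read.csv(csv1)
  truth <- sc$truth[order(sc$truth$template_id, sc$truth$row, sc$truth$col), ]
  expect_equal(got$anchor_row, truth$row)
  expect_equal(got$anchor_col, truth$col)
  expect_equal(got$template_id, truth$template_id)
  # overlay differs from the scene exactly on box perimeters
  overlay <- read_image(ov)
  expect_equal(sum(unclass(overlay) != unclass(sc$scene)),
               sum((2 * got$height + 2 * got$width - 4)))
  # no plants above a 0.99 threshold on an empty scene: empty report
  blank <- make_scene(54, size = c(64, 64), templates = list(a = make_template(55, c(8, 8))),
                      k_plants = 0)
  res0 <- run_detection(blank$scene, list(a = make_template(55, c(8, 8))),
                        threshold = 0.99)
  expect_equal(nrow(res0), 0L)
})
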