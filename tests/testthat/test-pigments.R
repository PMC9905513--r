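rgb_img <- function(colours, M = 2, N = 2) {
  # colours: list of c(r, g, b) recycled over pixels, column-major
  px <- array(0, c(M, N, 3))
  k <- 1L
  for (j in 1:N) for (i in 1:M) {
    px[i, j, ] <- colours[[(k - 1L) %% length(colours) + 1L]]
    k <- k + 1L
  }
  raster_image(px)
}

test_that("colour gating assigns pure hues to the right class masks", {
  img <- rgb_img(list(c(0, 0, 255),      # hue 240: blue
                      c(255, 10, 30),    # hue ~355: red via wraparound
                      c(230, 210, 40),   # hue ~54: yellow
                      c(20, 20, 25)))    # dark: below val_min
  masks <- suppressWarnings(classify_colours(img))
  expect_equal(sum(masks$blue), 1L)
  expect_equal(sum(masks$red), 1L)
  expect_equal(sum(masks$yellow), 1L)
  expect_true(masks$blue[1, 1])
  expect_true(masks$red[2, 1])
  expect_true(masks$yellow[1, 2])
  expect_false(any(masks$blue & masks$red) || any(masks$blue & masks$yellow))
  expect_error(classify_colours(raster_image(matrix(100, 4, 4))), "RGB")
})

test_that("a class covering almost no pixels triggers the low-contrast warning", {
  px <- array(0, c(50, 50, 3)); px[, , 3] <- 255      # all blue
  w <- capture_warnings(classify_colours(raster_image(px)))
  expect_true(any(grepl("low-contrast class 'yellow'", w)))
  expect_true(any(grepl("low-contrast class 'red'", w)))
})

test_that("crystal segmentation: centroid/area arithmetic and min-area filter", {
  mask <- matrix(FALSE, 10, 10)
  mask[3:4, 5:6] <- TRUE                  # 4-px square, rows 2-3 cols 4-5 (0-based)
  cr <- detect_crystals(mask, "blue", scale = 2)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$x_um, 5 / 2)            # centre at px (3, 5) -> 2.5 um
  expect_equal(cr$y_um, 3 / 2)
  expect_equal(cr$area_um2, 1)            # 4 px / (2 px/um)^2
  # two components separated by background
  mask[8:9, 1:2] <- TRUE
  expect_equal(nrow(detect_crystals(mask, scale = 2)), 2L)
  # sub-threshold speck dropped
  mask2 <- matrix(FALSE, 6, 6); mask2[2, 2] <- TRUE
  expect_equal(nrow(detect_crystals(mask2, scale = 1, min_area_px = 4)), 0L)
})

test_that("mosaic geometry validates step against extent and overlap", {
  mos <- tile_mosaic(c(2, 3), c(400, 400), scale = 2, overlap_frac = 0.15)
  expect_equal(mos$extent_um, c(200, 200))
  expect_equal(mos$step_um, c(170, 170))
  expect_silent(tile_mosaic(c(2, 3), c(400, 400), 2, 0.15, step_um = 170))
  expect_error(tile_mosaic(c(2, 3), c(400, 400), 2, 0.15, step_um = 150),
               "inconsistent mosaic geometry")
})

test_that("a crystal re-observed in the shared strip is kept once", {
  mos <- tile_mosaic(c(1, 2), c(200, 200), scale = 2, overlap_frac = 0.2)
  # tile extents: 100 um; tile 2 starts at x = 80; overlap strip x in [80, 100]
  cr <- rbind(crystal_df(90, 50, tile_row = 1, tile_col = 1),
              crystal_df(90.3, 50.1, tile_row = 1, tile_col = 2))  # same crystal
  res <- dedup_overlap(cr, mos, match_radius_um = 2)
  expect_equal(nrow(res$crystals), 1L)
  expect_equal(res$n_dropped, 1L)
  expect_equal(res$crystals$tile_col, 1)
  # distinct crystals 3 * radius apart in the strip: both kept
  cr2 <- rbind(crystal_df(85, 50, tile_row = 1, tile_col = 1),
               crystal_df(91, 50, tile_row = 1, tile_col = 2))
  expect_equal(nrow(dedup_overlap(cr2, mos, 2)$crystals), 2L)
  # different colours never match
  cr3 <- cr; cr3$colour <- c("blue", "red")
  expect_equal(nrow(dedup_overlap(cr3, mos, 2)$crystals), 2L)
})

test_that("common-area index is the mean adjacent-pair overlap fraction", {
  expect_equal(dedup_overlap(crystal_df(numeric(0), numeric(0)),
                             tile_mosaic(c(1, 2), c(100, 100), 1, 0.25))$common_area_index,
               0.25)
  expect_equal(dedup_overlap(crystal_df(numeric(0), numeric(0)),
                             tile_mosaic(c(2, 2), c(100, 100), 1, c(0.1, 0.3)))$common_area_index,
               (2 * 0.3 + 2 * 0.1) / 4)
  # zero-overlap mosaic: index 0 and nothing dropped
  mos0 <- tile_mosaic(c(1, 2), c(100, 100), 1, 0)
  cr <- rbind(crystal_df(99, 50, tile_row = 1, tile_col = 1),
              crystal_df(101, 50, tile_row = 1, tile_col = 2))
  res <- dedup_overlap(cr, mos0, 5)
  expect_equal(res$common_area_index, 0)
  expect_equal(res$n_dropped, 0L)
})

test_that("full-mosaic segmentation recovers planted crystals after dedup", {
  mo <- make_mosaic(19, layout = c(2, 2), tile_px = c(200, 200), scale = 2,
                    densities = c(blue = 0.004, red = 0.002))
  res <- mosaic_crystals(mo$mosaic)
  expect_equal(nrow(res$crystals), nrow(mo$truth))
  expect_equal(sort(table(res$crystals$colour)), sort(table(mo$truth$colour)))
  # centroid recovery within 1 px equivalent (0.5 um at 2 px/um),
  # matched truth -> nearest recovered crystal of the same colour
  for (i in seq_len(nrow(mo$truth))) {
    same <- res$crystals[res$crystals$colour == mo$truth$colour[i], ]
    d <- sqrt((same$x_um - mo$truth$x_um[i])^2 + (same$y_um - mo$truth$y_um[i])^2)
    expect_lt(min(d), 0.5)
  }
})
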