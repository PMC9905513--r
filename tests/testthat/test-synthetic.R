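test_that("scene generator: empty recipe gives a constant image", {
  sc <- make_scene(1, size = c(64, 64), templates = list(a = make_template(2, c(8, 8))),
                   k_plants = 0, noise_sd = 0)
  expect_equal(length(unique(as.vector(unclass(sc$scene)))), 1L)
  expect_equal(nrow(sc$truth), 0L)
})

test_that("scene generator is byte-identical per seed and leaves the RNG alone", {
  tmpl <- list(a = make_template(3, c(10, 12)))
  d <- withr::local_tempdir()
  set.seed(999); before <- runif(1)
  set.seed(999)
  p1 <- write_scene(make_scene(7, size = c(96, 96), templates = tmpl,
                               k_plants = 2, noise_sd = 4), d, "s1")
  after <- runif(1)
  expect_equal(after, before)           # generator restored the RNG state
  p2 <- write_scene(make_scene(7, size = c(96, 96), templates = tmpl,
                               k_plants = 2, noise_sd = 4), d, "s2")
  expect_identical(readBin(p1["image"], "raw", file.size(p1["image"])),
                   readBin(p2["image"], "raw", file.size(p2["image"])))
  expect_identical(readLines(p1["truth"]), readLines(p2["truth"]))
})

test_that("planted template peaks exactly at the truth anchor (cross-module)", {
  tmpl <- make_template(13, c(14, 17))
  sc <- make_scene(14, size = c(150, 150), templates = list(a = tmpl), k_plants = 1)
  cm <- correlation_map(sc$scene, template_pattern(unclass(tmpl)))
  peak <- which(cm$values == max(cm$values), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]) - 1L, c(sc$truth$row, sc$truth$col))
  expect_gte(max(cm$values), 1 - 1e-6)
})

test_that("unplaceable recipes fail loudly instead of under-planting", {
  tmpl <- make_template(4, c(30, 30))
  expect_error(make_scene(5, size = c(64, 64), templates = list(a = tmpl),
                          k_plants = 10),
               "placement error")
})

test_that("mosaic generator: zero densities give blank tiles and empty truth", {
  mo <- make_mosaic(21, layout = c(1, 2), tile_px = c(80, 80), scale = 2,
                    densities = c(blue = 0))
  expect_equal(nrow(mo$truth), 0L)
  t1 <- unclass(mo$mosaic$tiles[[1]][[1]])
  expect_equal(length(unique(as.vector(t1[, , 1]))), 1L)
})

test_that("mosaic generator is deterministic and truth flags re-observations", {
  mo1 <- make_mosaic(22, layout = c(2, 2), tile_px = c(150, 150), scale = 2,
                     densities = c(blue = 0.003))
  mo2 <- make_mosaic(22, layout = c(2, 2), tile_px = c(150, 150), scale = 2,
                     densities = c(blue = 0.003))
  expect_identical(mo1$truth, mo2$truth)
  expect_identical(unclass(mo1$mosaic$tiles[[2]][[1]]),
                   unclass(mo2$mosaic$tiles[[2]][[1]]))
  expect_true(any(mo1$truth$n_tiles > 1))      # some crystals sit in overlaps
  # every crystal is fully visible in at least one tile
  expect_true(all(mo1$truth$n_tiles >= 1))
})

test_that("a crystal planted in the shared strip dedups to one (3-4-5 check)", {
  # single tile, two blue crystals planted 3/4 um apart -> distance 5
  mo <- make_mosaic(30, layout = c(1, 1), tile_px = c(100, 100), scale = 2,
                    densities = c(blue = 0))
  # stamp two crystals manually through the pipeline by rendering a fresh
  # mosaic with exactly two planted centres via a tiny density and checking
  # the planted-truth path instead
  cr <- crystal_df(c(10, 13), c(10, 14))
  st <- pair_distances(cr, "blue")
  expect_equal(st$mean_um, 5)
  # 2-tile overlap dedup, end to end on rendered tiles
  found <- FALSE
  mo2 <- make_mosaic(31, layout = c(1, 2), tile_px = c(120, 120), scale = 2,
                     densities = c(blue = 0.004))
  res <- mosaic_crystals(mo2$mosaic)
  expect_equal(nrow(res$crystals), nrow(mo2$truth))
  if (any(mo2$truth$n_tiles > 1)) found <- TRUE
  expect_true(found)
})

test_that("infeasible hardcore density errors at the rejection cap", {
  # 0.01 crystals/um^2 cannot satisfy a 20 um hardcore separation
  expect_error(make_mosaic(9, layout = c(1, 1), tile_px = c(200, 200), scale = 2,
                           densities = c(blue = 0.01), min_sep_um = 20),
               "feasibility error")
})

test_that("station-log generator: amplitude 0 is constant, output reproducible", {
  vars0 <- list(temperature_c = list(mean = 20, amplitude = 0, peak_hour = 15, noise_sd = 0),
                rh_pct = list(mean = 60, amplitude = 0, peak_hour = 3, noise_sd = 0),
                co2_ppm = list(mean = 450, amplitude = 0, peak_hour = 15, noise_sd = 0),
                light = list(mean = 80, amplitude = 0, peak_hour = 12, noise_sd = 0))
  sl <- make_station_log(2, days = 2, vars = vars0)
  expect_true(all(sl$log$temperature_c == 20))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.csv"); f2 <- file.path(d, "b.csv")
  write_station_log(make_station_log(44, days = 2), f1)
  write_station_log(make_station_log(44, days = 2), f2)
  expect_identical(readLines(f1), readLines(f2))
})
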