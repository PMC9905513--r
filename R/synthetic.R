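# All generators are pure functions of their recipe: they run under a local
# RNG seeded from the recipe's `seed` field and restore the caller's RNG
# state afterwards, so the same recipe yields byte-identical outputs.
with_recipe_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Bilinear upsample of a coarse value grid to M x N (smooth random fields).
bilinear_field <- function(coarse, M, N) {
  gr <- nrow(coarse); gc <- ncol(coarse)
  stopifnot(gr >= 2, gc >= 2)
  ry <- seq(1, gr, length.out = M); rx <- seq(1, gc, length.out = N)
  y0 <- pmin(floor(ry), gr - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gc - 1L); fx <- rx - x0
  A <- coarse[y0, x0, drop = FALSE];     B <- coarse[y0, x0 + 1, drop = FALSE]
  C <- coarse[y0 + 1, x0, drop = FALSE]; D <- coarse[y0 + 1, x0 + 1, drop = FALSE]
  FY <- matrix(fy, M, N); FX <- matrix(fx, M, N, byrow = TRUE)
  A * (1 - FY) * (1 - FX) + B * (1 - FY) * FX + C * FY * (1 - FX) + D * FY * FX
}

#' Generate a synthetic deterioration-pattern template
#'
#' A smooth, non-constant 8-bit blob pattern (bilinearly upsampled seeded
#' coarse grid), standing in for a fluorescing colony pattern cut from a
#' UVF photograph. Default size 123 x 156, the resolution of the larger of
#' the two survey templates (the smaller was 83 x 95).
#'
#' @param seed Integer seed.
#' @param size `(m, n)` in pixels.
#' @param coarse Coarse-grid resolution controlling smoothness (default 8).
#' @param range Intensity range of the pattern.
#' @return A grayscale `raster_image`.
#' @export
make_template <- function(seed, size = c(123, 156), coarse = 8,
                          range = c(30, 220)) {
  with_recipe_seed(seed, {
    g <- matrix(stats::runif(coarse * coarse, range[1], range[2]),
                coarse, coarse)
    raster_image(floor(bilinear_field(g, size[1], size[2]) + 0.5))
  })
}

#' Generate a synthetic UVF scene with planted templates
#'
#' Plants non-overlapping copies of one or more templates into a background
#' (flat or smooth blotchy field), applies per-plant affine intensity jitter
#' (contrast `a`, brightness `b`: `a * T + b`), then global Gaussian pixel
#' noise, clamps to `[0, 255]` and rounds. The truth table lists the exact
#' 0-based anchor of every plant. Placement is rejection sampling with a cap
#' of `10 * total plants` attempts; an unplaceable recipe is an error, never
#' a silent under-planting.
#'
#' @param seed Integer seed.
#' @param size Scene `(M, N)` in pixels (default 1024 x 1024; the real
#'   panoramas are ~26,000 x 13,700 — fixtures stay desk-scale).
#' @param templates Named list of grayscale templates (`raster_image` or
#'   matrix); names become template ids.
#' @param k_plants Plants per template (recycled over templates).
#' @param noise_sd Global Gaussian noise SD in intensity units.
#' @param brightness_jitter Additive per-plant jitter range `c(lo, hi)`.
#' @param contrast_jitter Multiplicative per-plant jitter range `c(lo, hi)`.
#' @param background `"flat"` or `"blotch"`.
#' @param bg_value Flat-background intensity / blotch mid-level.
#' @return List `scene` (grayscale `raster_image`), `truth` (data frame
#'   `template_id`, `row`, `col`), `recipe`.
#' @export
make_scene <- function(seed, size = c(1024, 1024), templates,
                       k_plants = 1, noise_sd = 0,
                       brightness_jitter = c(0, 0),
                       contrast_jitter = c(1, 1),
                       background = c("flat", "blotch"), bg_value = 60) {
  background <- match.arg(background)
  if (!is.list(templates)) templates <- list(template = templates)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  k_plants <- rep(k_plants, length.out = length(templates))
  recipe <- list(seed = seed, size = size, k_plants = k_plants,
                 noise_sd = noise_sd, brightness_jitter = brightness_jitter,
                 contrast_jitter = contrast_jitter, background = background,
                 bg_value = bg_value)
  M <- size[1]; N <- size[2]
  for (tp in templates)
    stopifnot(nrow(tp) <= M, ncol(tp) <= N)
  with_recipe_seed(seed, {
    scene <- if (background == "flat") {
      matrix(bg_value, M, N)
    } else {
      g <- matrix(stats::runif(81, bg_value - 25, bg_value + 25), 9, 9)
      bilinear_field(g, M, N)
    }
    total_k <- sum(k_plants)
    budget <- 10L * max(total_k, 1L)
    placed <- data.frame(template_id = character(0), row = integer(0),
                         col = integer(0), stringsAsFactors = FALSE)
    boxes <- matrix(numeric(0), ncol = 4)         # r0, c0, r1, c1 (0-based)
    for (ti in seq_along(templates)) {
      tp <- unclass(templates[[ti]])
      m <- nrow(tp); n <- ncol(tp)
      for (k in seq_len(k_plants[ti])) {
        ok <- FALSE
        while (budget > 0L) {
          budget <- budget - 1L
          r0 <- sample.int(M - m + 1L, 1L) - 1L
          c0 <- sample.int(N - n + 1L, 1L) - 1L
          if (nrow(boxes) == 0 ||
              !any(r0 <= boxes[, 3] & r0 + m - 1 >= boxes[, 1] &
                   c0 <= boxes[, 4] & c0 + n - 1 >= boxes[, 2])) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("placement error: could not plant ", total_k,
                      " non-overlapping templates within the attempt budget")
        a <- stats::runif(1, contrast_jitter[1], contrast_jitter[2])
        b <- stats::runif(1, brightness_jitter[1], brightness_jitter[2])
        scene[(r0 + 1):(r0 + m), (c0 + 1):(c0 + n)] <- a * tp + b
        boxes <- rbind(boxes, c(r0, c0, r0 + m - 1, c0 + n - 1))
        placed <- rbind(placed, data.frame(template_id = names(templates)[ti],
                                           row = r0, col = c0,
                                           stringsAsFactors = FALSE))
      }
    }
    if (noise_sd > 0)
      scene <- scene + matrix(stats::rnorm(M * N, 0, noise_sd), M, N)
    scene <- floor(pmin(pmax(scene, 0), 255) + 0.5)
    list(scene = raster_image(scene), truth = placed, recipe = recipe)
  })
}

#' Write a synthetic scene and its truth file
#'
#' @param sc Result of [make_scene()].
#' @param dir Output directory (created if needed).
#' @param name Basename (default `"scene"`).
#' @return Paths of the written files, invisibly.
#' @export
write_scene <- function(sc, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- file.path(dir, paste0(name, ".png"))
  tru <- file.path(dir, paste0(name, "_truth.json"))
  write_image(sc$scene, img)
  jsonlite::write_json(sc$truth, tru, dataframe = "rows", digits = NA)
  invisible(c(image = img, truth = tru))
}

hsv_to_rgb255 <- function(h, s, v) {
  as.integer(grDevices::col2rgb(grDevices::hsv(h %% 360 / 360, s, v)))
}

#' Generate a synthetic crystal mosaic with ground truth
#'
#' Plants a hardcore point process of pigment crystals (minimum separation
#' `min_sep_um` between any two centres, all colours) over the global extent
#' of a tiled mosaic and renders each tile: crystals are filled axis-aligned
#' ellipses in their class colour with per-crystal hue/sat/value jitter kept
#' inside the class gates, on a dark background. The default blue density
#' 0.01 crystals/um^2 mirrors the observed ~20 crystals per 2000 um^2.
#'
#' A crystal is rendered in a tile only when its full extent fits inside
#' that tile's field of view; positions that fit no tile are rejected during
#' placement. Crystals inside overlap strips are therefore rendered
#' identically in every covering tile — exact re-observations, which is what
#' overlap deduplication removes. Placement is rejection sampling capped at
#' `200 * n + 1000` attempts; a density infeasible under `min_sep_um` is an
#' error.
#'
#' @param seed Integer seed.
#' @param layout Tile grid `(rows, cols)`.
#' @param tile_px Tile size `(height, width)` pixels.
#' @param scale Pixels per um.
#' @param overlap_frac Per-axis overlap fraction in `[0, 1)`.
#' @param densities Named vector, crystals per um^2 per colour class
#'   (default `c(blue = 0.01)`).
#' @param min_sep_um Hardcore minimum centre separation, um.
#' @param radius_um Ellipse semi-axis range `c(lo, hi)`, um.
#' @param bg_value Background RGB (dark, below the value gate).
#' @return List `mosaic` (a [tile_mosaic()] with rendered tiles), `truth`
#'   (data frame: `id`, `x_um`, `y_um`, `colour`, `rx_um`, `ry_um`,
#'   `tile_row`, `tile_col` of the first covering tile, `n_tiles`),
#'   `recipe`.
#' @export
make_mosaic <- function(seed, layout = c(2, 2), tile_px = c(400, 400),
                        scale = 2, overlap_frac = 0.15,
                        densities = c(blue = 0.01), min_sep_um = 4,
                        radius_um = c(0.8, 1.6), bg_value = c(25, 25, 32)) {
  recipe <- as.list(environment())
  mos <- tile_mosaic(layout, tile_px, scale, overlap_frac)
  ext <- mosaic_extent_um(mos)
  rmax <- radius_um[2]
  base_hue <- c(blue = 230, yellow = 55, red = 355)
  if (!all(names(densities) %in% names(base_hue)))
    stop("densities must be named with classes: ", paste(names(base_hue), collapse = ", "))
  with_recipe_seed(seed, {
    n_per <- round(densities * ext["x"] * ext["y"])
    n_tot <- sum(n_per)
    xs <- ys <- rxs <- rys <- hs <- ss <- vs <- numeric(0)
    cols <- character(0)
    budget <- 200L * max(n_tot, 1L) + 1000L
    fully_in_some_tile <- function(x, y, r) {
      for (tr in seq_len(layout[1])) for (tc in seq_len(layout[2])) {
        o <- tile_origin_um(mos, tr, tc)
        if (x - r >= o["x"] && x + r <= o["x"] + mos$extent_um[2] &&
            y - r >= o["y"] && y + r <= o["y"] + mos$extent_um[1])
          return(TRUE)
      }
      FALSE
    }
    for (cls in names(densities)) {
      for (k in seq_len(n_per[[cls]])) {
        ok <- FALSE
        while (budget > 0L) {
          budget <- budget - 1L
          rx <- stats::runif(1, radius_um[1], radius_um[2])
          ry <- stats::runif(1, radius_um[1], radius_um[2])
          r <- max(rx, ry)
          x <- stats::runif(1, rmax, ext["x"] - rmax)
          y <- stats::runif(1, rmax, ext["y"] - rmax)
          if (!fully_in_some_tile(x, y, r)) next
          if (length(xs) > 0 &&
              min((xs - x)^2 + (ys - y)^2) < min_sep_um^2) next
          ok <- TRUE; break
        }
        if (!ok)
          stop("feasibility error: density infeasible under min_sep_um = ",
               min_sep_um, " (rejection cap reached)")
        xs <- c(xs, x); ys <- c(ys, y); rxs <- c(rxs, rx); rys <- c(rys, ry)
        cols <- c(cols, cls)
        hs <- c(hs, base_hue[[cls]] + stats::runif(1, -10, 10))
        ss <- c(ss, stats::runif(1, 0.65, 0.85))
        vs <- c(vs, stats::runif(1, 0.75, 0.95))
      }
    }
    # render tiles
    tiles <- vector("list", layout[1])
    th <- tile_px[1]; tw <- tile_px[2]
    first_tile <- matrix(NA_integer_, length(xs), 2)
    n_tiles <- integer(length(xs))
    for (tr in seq_len(layout[1])) {
      tiles[[tr]] <- vector("list", layout[2])
      for (tc in seq_len(layout[2])) {
        o <- tile_origin_um(mos, tr, tc)
        px <- array(0, dim = c(th, tw, 3))
        for (ch in 1:3) px[, , ch] <- bg_value[ch]
        for (i in seq_along(xs)) {
          r <- max(rxs[i], rys[i])
          if (!(xs[i] - r >= o["x"] && xs[i] + r <= o["x"] + mos$extent_um[2] &&
                ys[i] - r >= o["y"] && ys[i] + r <= o["y"] + mos$extent_um[1]))
            next
          n_tiles[i] <- n_tiles[i] + 1L
          if (is.na(first_tile[i, 1])) first_tile[i, ] <- c(tr, tc)
          cx <- (xs[i] - o["x"]) * scale; cy <- (ys[i] - o["y"]) * scale
          rxp <- rxs[i] * scale; ryp <- rys[i] * scale
          rlo <- max(1L, floor(cy - ryp)); rhi <- min(th, ceiling(cy + ryp) + 1L)
          clo <- max(1L, floor(cx - rxp)); chi <- min(tw, ceiling(cx + rxp) + 1L)
          rgbv <- hsv_to_rgb255(hs[i], ss[i], vs[i])
          for (rr in rlo:rhi) for (cc in clo:chi) {
            if (((cc - 0.5 - cx) / rxp)^2 + ((rr - 0.5 - cy) / ryp)^2 <= 1)
              px[rr, cc, ] <- rgbv
          }
        }
        tiles[[tr]][[tc]] <- raster_image(px)
      }
    }
    truth <- data.frame(id = seq_along(xs), x_um = xs, y_um = ys,
                        colour = cols, rx_um = rxs, ry_um = rys,
                        tile_row = first_tile[, 1], tile_col = first_tile[, 2],
                        n_tiles = n_tiles, stringsAsFactors = FALSE)
    mos$tiles <- tiles
    list(mosaic = mos, truth = truth, recipe = recipe)
  })
}

#' Write mosaic tiles, manifest and truth
#'
#' Tiles are written as `tile_<row>_<col>.png`; the manifest JSON records
#' layout, tile size, scale, overlap and file names.
#'
#' @param mo Result of [make_mosaic()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_mosaic <- function(mo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mos <- mo$mosaic
  files <- character(0)
  for (tr in seq_len(mos$layout[1])) for (tc in seq_len(mos$layout[2])) {
    f <- sprintf("tile_%d_%d.png", tr, tc)
    write_image(mos$tiles[[tr]][[tc]], file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- list(layout = mos$layout, tile_px = mos$tile_px,
                   scale = mos$scale, overlap_frac = mos$overlap_frac,
                   step_um = mos$step_um, tiles = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(mo$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(file.path(dir, c(files, "manifest.json", "truth.json")))
}

#' Generate a synthetic monitoring-station log
#'
#' Sinusoidal diurnal cycles plus seeded Gaussian noise for temperature,
#' relative humidity, CO2 and light:
#' `mean + amplitude * cos(2 * pi * (hour - peak_hour - 0.5) / 24) + noise`.
#' `peak_hour` names the clock *hour* of the diurnal maximum (the 60-minute
#' bin [summarize_log()] reports), so the continuous sinusoid peaks at that
#' hour's centre.
#' Defaults emulate the monitored room: temperature mean 23.5 C peaking at
#' 15:00 (trough 03:00), relative humidity mean 72.7% in anti-phase, CO2
#' mean 570 ppm. RH is clamped to `[0, 100]` and light to `>= 0`.
#'
#' @param seed Integer seed.
#' @param days Number of days (>= 2).
#' @param step_min Sampling interval, minutes.
#' @param start Start timestamp (parsed as UTC).
#' @param vars Named list per variable: `mean`, `amplitude`, `peak_hour`,
#'   `noise_sd`.
#' @return List `log` (data frame `timestamp,temperature_c,rh_pct,co2_ppm,light`),
#'   `truth` (the configured means/peak hours), `recipe`.
#' @export
make_station_log <- function(seed, days = 3, step_min = 10,
                             start = "2021-07-01 00:00:00",
                             vars = list(
                               temperature_c = list(mean = 23.5, amplitude = 1.5,
                                                    peak_hour = 15, noise_sd = 0.1),
                               rh_pct = list(mean = 72.7, amplitude = 4,
                                             peak_hour = 3, noise_sd = 0.5),
                               co2_ppm = list(mean = 570, amplitude = 30,
                                              peak_hour = 15, noise_sd = 5),
                               light = list(mean = 120, amplitude = 80,
                                            peak_hour = 12, noise_sd = 5))) {
  stopifnot(days >= 2)
  recipe <- list(seed = seed, days = days, step_min = step_min,
                 start = start, vars = vars)
  t0 <- as.POSIXct(start, tz = "UTC")
  n <- as.integer(days * 24 * 60 / step_min)
  ts <- t0 + seq(0, by = step_min * 60, length.out = n)
  hour_frac <- (as.numeric(ts - t0, units = "hours") +
                as.POSIXlt(t0)$hour) %% 24
  with_recipe_seed(seed, {
    df <- data.frame(timestamp = ts)
    for (v in names(vars)) {
      p <- vars[[v]]
      x <- p$mean + p$amplitude *
        cos(2 * pi * (hour_frac - p$peak_hour - 0.5) / 24)
      if (p$noise_sd > 0) x <- x + stats::rnorm(n, 0, p$noise_sd)
      if (v == "rh_pct") x <- pmin(pmax(x, 0), 100)
      if (v == "light") x <- pmax(x, 0)
      df[[v]] <- x
    }
    truth <- lapply(vars, function(p) p[c("mean", "amplitude", "peak_hour")])
    list(log = df, truth = truth, recipe = recipe)
  })
}

#' Write a station log as CSV (ISO-8601 timestamps) plus truth JSON
#'
#' @param sl Result of [make_station_log()].
#' @param path CSV path; truth goes to `<path basename>_truth.json`.
#' @return Paths written, invisibly.
#' @export
write_station_log <- function(sl, path) {
  df <- sl$log
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  tru <- sub("\\.csv$", "", path)
  tru <- paste0(tru, "_truth.json")
  jsonlite::write_json(sl$truth, tru, auto_unbox = TRUE, digits = NA)
  invisible(c(log = path, truth = tru))
}
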