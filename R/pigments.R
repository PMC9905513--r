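#' Colour-class specification for pigment crystals
#'
#' A pigment class is gated in hue/saturation/value space: one or more hue
#' intervals in degrees (wraparound allowed, e.g. red 330-20), a minimum
#' saturation and a minimum value. Pixels failing every gate are background.
#'
#' @param name Class name (e.g. `"blue"`).
#' @param hue_ranges List of `c(lo, hi)` degree intervals in `[0, 360)`;
#'   `lo > hi` wraps through 0.
#' @param sat_min,val_min Fractions in `[0, 1]`.
#' @return A `colour_class_spec`.
#' @export
colour_class_spec <- function(name, hue_ranges, sat_min = 0.3, val_min = 0.2) {
  if (is.numeric(hue_ranges)) hue_ranges <- list(hue_ranges)
  stopifnot(length(hue_ranges) >= 1,
            sat_min >= 0, sat_min <= 1, val_min >= 0, val_min <= 1)
  for (h in hue_ranges) stopifnot(length(h) == 2, all(h >= 0), all(h < 360))
  structure(list(name = name, hue_ranges = hue_ranges,
                 sat_min = sat_min, val_min = val_min),
            class = "colour_class_spec")
}

#' Default pigment classes: ultramarine blue, chrome yellow, vermilion red
#'
#' Hue gates: blue 190-270, yellow 40-70, red 330-20 (wrapping through 0);
#' saturation >= 0.3, value >= 0.2 for all three.
#'
#' @return Named list of [colour_class_spec()].
#' @export
default_colour_classes <- function() {
  list(blue   = colour_class_spec("blue",   c(190, 270)),
       yellow = colour_class_spec("yellow", c(40, 70)),
       red    = colour_class_spec("red",    c(330, 20)))
}

hue_in <- function(h, range) {
  if (range[1] <= range[2]) h >= range[1] & h <= range[2]
  else h >= range[1] | h <= range[2]     # wraparound
}

#' Classify pixels into pigment colour classes
#'
#' Converts the RGB image to HSV and assigns each pixel to the first class
#' (in list order) whose hue/saturation/value window contains it, so the
#' masks are mutually exclusive. Dark-layer caveat: light pigments on dark
#' grounds segment poorly; a class whose mask covers less than 0.05% of the
#' pixels triggers a low-contrast warning naming the class.
#'
#' @param img RGB `raster_image`.
#' @param specs List of [colour_class_spec()] (default
#'   [default_colour_classes()]).
#' @param warn_low_coverage Emit the low-coverage warning (default `TRUE`).
#' @return Named list of logical matrices, one mask per class.
#' @export
classify_colours <- function(img, specs = default_colour_classes(),
                             warn_low_coverage = TRUE) {
  img <- as_raster_image(img)
  if (img_channels(img) != 3L)
    stop("colour classification requires an RGB image")
  px <- unclass(img)
  M <- dim(px)[1]; N <- dim(px)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
                            b = as.vector(px[, , 3]), maxColorValue = 255)
  h <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
  assigned <- rep(FALSE, M * N)
  masks <- list()
  for (spec in specs) {
    in_hue <- Reduce(`|`, lapply(spec$hue_ranges, function(r) hue_in(h, r)))
    hit <- !assigned & in_hue & s >= spec$sat_min & v >= spec$val_min
    assigned <- assigned | hit
    masks[[spec$name]] <- matrix(hit, M, N)
    if (warn_low_coverage && mean(hit) < 5e-4)
      warning("low-contrast class '", spec$name,
              "': mask covers < 0.05% of pixels", call. = FALSE)
  }
  masks
}

#' Segment crystals from a class mask
#'
#' 8-connected components of the mask with at least `min_area_px` pixels
#' become crystals. The centroid is the unweighted mean of the pixel-centre
#' coordinates (pixel `(r, c)` has centre `(r + 0.5, c + 0.5)` in pixel
#' units), converted to micrometres with `scale` (px/um); the area is the
#' pixel count divided by `scale^2`. Coordinates are tile-local:
#' `x_um` along columns, `y_um` along rows.
#'
#' @param mask Logical matrix.
#' @param colour Class name recorded on each crystal.
#' @param scale Pixels per micrometre (> 0).
#' @param min_area_px Minimum component area in pixels (default 4;
#'   sub-resolution specks are noise).
#' @param tile Optional `(row, col)` tile index recorded on each crystal.
#' @return Data frame `x_um`, `y_um`, `colour`, `area_um2`, `n_px`,
#'   `tile_row`, `tile_col` — one row per crystal (possibly empty).
#' @export
detect_crystals <- function(mask, colour = "crystal", scale, min_area_px = 4,
                            tile = c(NA_integer_, NA_integer_)) {
  stopifnot(is.logical(mask), is.matrix(mask), scale > 0, min_area_px >= 1)
  lab <- label_components(mask)
  rows <- list()
  if (lab$n > 0L) {
    for (g in seq_len(lab$n)) {
      px <- lab$coords[lab$membership == g, , drop = FALSE]
      if (nrow(px) < min_area_px) next
      cy <- mean(px[, 1] - 0.5)            # 1-based index - 0.5 = centre
      cx <- mean(px[, 2] - 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        x_um = cx / scale, y_um = cy / scale, colour = colour,
        area_um2 = nrow(px) / scale^2, n_px = nrow(px),
        tile_row = tile[1], tile_col = tile[2], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      colour = character(0), area_um2 = numeric(0),
                      n_px = integer(0), tile_row = integer(0),
                      tile_col = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$y_um, out$x_um), , drop = FALSE]
}

#' Tiled micrograph mosaic geometry
#'
#' Adjacent micrographs are acquired by stepping the microscope stage a
#' known distance so that neighbouring tiles overlap. Tile `(r, c)`
#' (1-based) has its top-left corner at
#' `(x, y) = ((c-1) * step_x, (r-1) * step_y)` um, where
#' `step = extent * (1 - overlap_frac)` and `extent = tile_px / scale`.
#' A tile-local point maps to global um as `origin + local / scale`.
#'
#' @param layout `(rows, cols)` of the tile grid.
#' @param tile_px `(height, width)` of each tile in pixels.
#' @param scale Pixels per micrometre (> 0).
#' @param overlap_frac Fraction of the tile extent shared with each
#'   neighbour, per axis (`(y, x)` or scalar), in `[0, 1)`.
#' @param step_um Optional explicit `(y, x)` stage step in um; must agree
#'   with `extent * (1 - overlap_frac)` to 1e-6 relative or a geometry
#'   error is raised.
#' @param tiles Optional list of tile images indexed `[[row]][[col]]`.
#' @return A `tile_mosaic`.
#' @export
tile_mosaic <- function(layout, tile_px, scale, overlap_frac = 0,
                        step_um = NULL, tiles = NULL) {
  stopifnot(length(layout) == 2, all(layout >= 1), scale > 0)
  if (length(overlap_frac) == 1L) overlap_frac <- rep(overlap_frac, 2L)
  if (length(tile_px) == 1L) tile_px <- rep(tile_px, 2L)
  stopifnot(all(overlap_frac >= 0), all(overlap_frac < 1))
  extent_um <- tile_px / scale                       # (y, x)
  implied_step <- extent_um * (1 - overlap_frac)
  if (is.null(step_um)) {
    step_um <- implied_step
  } else {
    if (length(step_um) == 1L) step_um <- rep(step_um, 2L)
    if (any(abs(step_um - implied_step) > 1e-6 * pmax(implied_step, 1)))
      stop("inconsistent mosaic geometry: step_um != extent * (1 - overlap)")
  }
  structure(list(layout = as.integer(layout), tile_px = as.integer(tile_px),
                 scale = scale, overlap_frac = overlap_frac,
                 extent_um = extent_um, step_um = step_um, tiles = tiles),
            class = "tile_mosaic")
}

tile_origin_um <- function(mosaic, tr, tc) {
  c(x = (tc - 1) * mosaic$step_um[2], y = (tr - 1) * mosaic$step_um[1])
}

mosaic_extent_um <- function(mosaic) {
  c(x = (mosaic$layout[2] - 1) * mosaic$step_um[2] + mosaic$extent_um[2],
    y = (mosaic$layout[1] - 1) * mosaic$step_um[1] + mosaic$extent_um[1])
}

# is global point (x, y) inside the field of view of tile (tr, tc)?
point_in_tile <- function(mosaic, x, y, tr, tc) {
  o <- tile_origin_um(mosaic, tr, tc)
  x >= o["x"] & x <= o["x"] + mosaic$extent_um[2] &
  y >= o["y"] & y <= o["y"] + mosaic$extent_um[1]
}

#' Deduplicate crystals re-observed in overlapping tiles
#'
#' Tiles are visited in raster order. A crystal from a later tile is dropped
#' when its centroid lies inside the field of view of an earlier adjacent
#' tile (left or up) AND a crystal of the same colour is already kept within
#' `match_radius_um`; distinct crystals that merely sit in the shared strip
#' are both kept. Also reports the common-area index: the mean pairwise
#' overlap fraction (intersection area / tile area) over 4-adjacent tile
#' pairs — the error-reduction index for distances measured across
#' neighbouring photographs.
#'
#' @param crystals Data frame as from [detect_crystals()], with global
#'   `x_um`/`y_um` (see [mosaic_crystals()]) and tile indices.
#' @param mosaic A [tile_mosaic()].
#' @param match_radius_um Same-crystal match radius, um (default 2).
#' @return List: `crystals` (deduplicated, raster-ordered),
#'   `common_area_index`, `n_dropped`.
#' @export
dedup_overlap <- function(crystals, mosaic, match_radius_um = 2) {
  stopifnot(inherits(mosaic, "tile_mosaic"))
  if (nrow(crystals) > 0 && anyNA(crystals$tile_row))
    stop("crystals must carry tile indices for dedup")
  nr <- mosaic$layout[1]; nc <- mosaic$layout[2]
  # common-area index over 4-adjacent pairs
  fr_x <- mosaic$overlap_frac[2]; fr_y <- mosaic$overlap_frac[1]
  n_h <- nr * (nc - 1); n_v <- (nr - 1) * nc
  common_area_index <- if (n_h + n_v == 0) 0 else
    (n_h * fr_x + n_v * fr_y) / (n_h + n_v)

  if (nrow(crystals) == 0)
    return(list(crystals = crystals, common_area_index = common_area_index,
                n_dropped = 0L))
  rank <- (crystals$tile_row - 1) * nc + crystals$tile_col
  ord <- order(rank, crystals$y_um, crystals$x_um)
  crystals <- crystals[ord, , drop = FALSE]
  keep <- logical(nrow(crystals))
  kx <- ky <- numeric(0); kcol <- character(0)
  for (i in seq_len(nrow(crystals))) {
    tr <- crystals$tile_row[i]; tc <- crystals$tile_col[i]
    x <- crystals$x_um[i]; y <- crystals$y_um[i]
    in_prior_overlap <-
      (tc > 1 && point_in_tile(mosaic, x, y, tr, tc - 1)) ||
      (tr > 1 && point_in_tile(mosaic, x, y, tr - 1, tc))
    dup <- FALSE
    if (in_prior_overlap && length(kx) > 0) {
      same <- kcol == crystals$colour[i]
      if (any(same))
        dup <- min((kx[same] - x)^2 + (ky[same] - y)^2) <= match_radius_um^2
    }
    keep[i] <- !dup
    if (!dup) {
      kx <- c(kx, x); ky <- c(ky, y); kcol <- c(kcol, crystals$colour[i])
    }
  }
  out <- crystals[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(crystals = out, common_area_index = common_area_index,
       n_dropped = sum(!keep))
}

#' Segment a whole mosaic into a global crystal list
#'
#' Runs [classify_colours()] + [detect_crystals()] on every tile, lifts
#' tile-local centroids to the global mosaic frame, and removes
#' re-observations with [dedup_overlap()].
#'
#' @param mosaic A [tile_mosaic()] whose `tiles` are RGB images.
#' @param specs Colour classes.
#' @param min_area_px Passed to [detect_crystals()].
#' @param match_radius_um Passed to [dedup_overlap()].
#' @param warn_low_coverage Passed to [classify_colours()].
#' @return As [dedup_overlap()].
#' @export
mosaic_crystals <- function(mosaic, specs = default_colour_classes(),
                            min_area_px = 4, match_radius_um = 2,
                            warn_low_coverage = FALSE) {
  stopifnot(inherits(mosaic, "tile_mosaic"), !is.null(mosaic$tiles))
  all_cr <- list()
  for (tr in seq_len(mosaic$layout[1])) {
    for (tc in seq_len(mosaic$layout[2])) {
      img <- mosaic$tiles[[tr]][[tc]]
      masks <- classify_colours(img, specs, warn_low_coverage = warn_low_coverage)
      o <- tile_origin_um(mosaic, tr, tc)
      for (cls in names(masks)) {
        cr <- detect_crystals(masks[[cls]], colour = cls,
                              scale = mosaic$scale, min_area_px = min_area_px,
                              tile = c(tr, tc))
        if (nrow(cr) > 0) {
          cr$x_um <- cr$x_um + o["x"]
          cr$y_um <- cr$y_um + o["y"]
          all_cr[[length(all_cr) + 1L]] <- cr
        }
      }
    }
  }
  crystals <- if (length(all_cr)) do.call(rbind, all_cr) else
    detect_crystals(matrix(FALSE, 1, 1), scale = 1)
  rownames(crystals) <- NULL
  dedup_overlap(crystals, mosaic, match_radius_um)
}
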