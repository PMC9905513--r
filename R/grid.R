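#' Sampling-grid configuration
#'
#' The survey grid overlaid on a painting: P x Q numbered cells (row-major
#' from 1 at top-left), each cell subdivided into subcolumns A-D
#' (left to right) and subrows 1-3 (top to bottom), so a spot reads e.g.
#' `"63C3"`. The cell count of the original survey is not fixed here: P and
#' Q are configuration.
#'
#' @param rows,cols Number of cell rows (P) and columns (Q), both >= 1.
#' @return A `grid_config` object.
#' @export
grid_config <- function(rows = 10L, cols = 10L) {
  stopifnot(rows >= 1, cols >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "grid_config")
}

# Strip index of coordinate x among k equal strips over [0, extent].
# Strips are (b_{i}, b_{i+1}] except the first, which is [0, b_1]: a pixel
# sitting exactly on an interior boundary belongs to the lower-indexed strip.
strip_index <- function(x, extent, k) {
  idx <- ceiling(x * k / extent) - 1
  pmin(pmax(idx, 0), k - 1)
}

# 0-based pixel range [lo, hi] of strip i (0-based) among k strips over
# [0, extent); inverse of strip_index over integer pixels.
strip_pixels <- function(i, extent, k) {
  b_lo <- i * extent / k
  b_hi <- (i + 1) * extent / k
  lo <- if (i == 0) 0 else floor(b_lo) + 1
  hi <- min(floor(b_hi), extent - 1)
  c(lo, hi)
}

#' Map a pixel to its grid reference
#'
#' @param row,col 0-based pixel coordinates.
#' @param M,N Image height and width in pixels.
#' @param grid A [grid_config()].
#' @return A `grid_ref` list with fields `cell`, `subcolumn` (`"A"`-`"D"`),
#'   `subrow` (1-3) and `label` (e.g. `"63C3"`).
#' @export
pixel_to_gridref <- function(row, col, M, N, grid = grid_config()) {
  if (row < 0 || row >= M || col < 0 || col >= N)
    stop(sprintf("pixel (%s, %s) outside the %d x %d image", row, col, M, N))
  P <- grid$rows; Q <- grid$cols
  cr <- strip_index(row, M, P)
  cc <- strip_index(col, N, Q)
  cell <- cr * Q + cc + 1L
  # subcell strips within this cell's continuous span
  row0 <- cr * M / P; col0 <- cc * N / Q
  sr <- strip_index(row - row0, M / P, 3L)
  sc <- strip_index(col - col0, N / Q, 4L)
  subcolumn <- LETTERS[sc + 1L]
  subrow <- as.integer(sr + 1L)
  structure(list(cell = as.integer(cell), subcolumn = subcolumn,
                 subrow = subrow,
                 label = paste0(cell, subcolumn, subrow)),
            class = "grid_ref")
}

#' @export
print.grid_ref <- function(x, ...) {
  cat("<grid_ref ", x$label, ">\n", sep = "")
  invisible(x)
}

#' Parse a grid label such as `"63C3"`
#'
#' @param label Character label: cell number, subcolumn letter, subrow digit.
#' @param grid A [grid_config()] used to validate the cell number.
#' @return A `grid_ref`.
#' @export
parse_gridref <- function(label, grid = grid_config()) {
  m <- regmatches(label, regexec("^([0-9]+)([A-D])([1-3])$", label))[[1]]
  if (length(m) != 4L) stop("malformed grid label: ", label)
  cell <- as.integer(m[2])
  if (cell < 1L || cell > grid$rows * grid$cols)
    stop("cell ", cell, " outside the ", grid$rows, " x ", grid$cols, " grid")
  structure(list(cell = cell, subcolumn = m[3], subrow = as.integer(m[4]),
                 label = label),
            class = "grid_ref")
}

#' Pixel rectangle covered by a grid reference
#'
#' Left inverse of [pixel_to_gridref()]: every pixel of the returned box maps
#' back to the same label.
#'
#' @param ref A `grid_ref` or label string.
#' @inheritParams pixel_to_gridref
#' @return A [pixel_box()].
#' @export
gridref_to_box <- function(ref, M, N, grid = grid_config()) {
  if (is.character(ref)) ref <- parse_gridref(ref, grid)
  P <- grid$rows; Q <- grid$cols
  cr <- (ref$cell - 1L) %/% Q
  cc <- (ref$cell - 1L) %% Q
  sr <- ref$subrow - 1L
  sc <- match(ref$subcolumn, LETTERS[1:4]) - 1L
  # subcell strip s within cell c spans strips of the composite subdivision:
  # rows are split into P*3 pieces, row strip index = cr*3 + sr
  rr <- strip_pixels_nested(cr, sr, M, P, 3L)
  cm <- strip_pixels_nested(cc, sc, N, Q, 4L)
  pixel_box(rr[1], cm[1], rr[2] - rr[1] + 1L, cm[2] - cm[1] + 1L)
}

# pixels whose cell strip is `ci` (of k1) AND whose subcell strip is `si`
# (of k2 within that cell)
strip_pixels_nested <- function(ci, si, extent, k1, k2) {
  b_cell <- ci * extent / k1
  lo_cont <- b_cell + si * extent / (k1 * k2)
  hi_cont <- b_cell + (si + 1) * extent / (k1 * k2)
  lo <- if (ci == 0 && si == 0) 0 else floor(lo_cont) + 1
  hi <- min(floor(hi_cont), extent - 1)
  if (lo > hi) stop("degenerate grid strip: grid finer than the image")
  c(lo, hi)
}
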