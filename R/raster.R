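#' Raster image container
#'
#' A `raster_image` is a numeric matrix (grayscale) or an M x N x 3 array
#' (RGB) with 8-bit intensities in `[0, 255]`, row index growing downward
#' from a top-left origin. All pixel coordinates in the package are 0-based
#' `(row, col)` pairs and all boxes are half-open.
#'
#' @param pixels Numeric matrix (M x N) or array (M x N x 3).
#' @param float If `TRUE`, intensities may be arbitrary reals (used
#'   internally after grayscale conversion or jitter); otherwise they must be
#'   integers in `[0, 255]`.
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels, float = FALSE) {
  if (is.null(dim(pixels))) stop("`pixels` must be a matrix or 3-d array")
  nd <- length(dim(pixels))
  if (!(nd == 2L || (nd == 3L && dim(pixels)[3] %in% c(1L, 3L))))
    stop("raster_image must have 1 or 3 channels")
  if (nd == 3L && dim(pixels)[3] == 1L) {
    pixels <- pixels[, , 1L, drop = TRUE]
    dim(pixels) <- dim(pixels)[1:2]
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be >= 1")
  if (!float) {
    if (anyNA(pixels)) stop("pixel intensities must not be NA")
    if (min(pixels) < 0 || max(pixels) > 255)
      stop("8-bit intensities must lie in [0, 255]")
    if (any(pixels != round(pixels)))
      stop("8-bit intensities must be integers (use float = TRUE for reals)")
  }
  structure(pixels, class = c("raster_image", class(unclass(pixels))))
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf("<raster_image %d x %d, %d channel%s, range [%g, %g]>\n",
              d[1], d[2], ch, if (ch > 1) "s" else "",
              min(x), max(x)))
  invisible(x)
}

#' @rdname raster_image
#' @param x Object to coerce.
#' @export
as_raster_image <- function(x, float = FALSE) {
  if (inherits(x, "raster_image")) return(x)
  raster_image(x, float = float)
}

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]
img_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3] else 1L

#' Read a PNG or TIFF image
#'
#' PNG decoding is delegated to the \pkg{png} package; TIFF support is a
#' built-in baseline codec (uncompressed, 8-bit, chunky). 16-bit inputs are
#' rescaled to 8-bit with a warning; an alpha channel is dropped with a
#' warning.
#'
#' @param path Path to an existing `.png`, `.tif` or `.tiff` file.
#' @return A `raster_image` (grayscale matrix or RGB array, 8-bit).
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("`path` must be a single file path")
  if (!file.exists(path)) stop("image file not found: ", path)
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (!is.null(info$bit.depth) && info$bit.depth == 16L)
      warning("16-bit PNG rescaled to 8-bit: ", path)
    px <- floor(arr * 255 + 0.5)
    if (length(dim(px)) == 3L) {
      nc <- dim(px)[3]
      if (nc == 2L) {            # gray + alpha
        warning("alpha channel dropped: ", path)
        px <- px[, , 1L]
      } else if (nc == 4L) {     # RGBA
        warning("alpha channel dropped: ", path)
        px <- px[, , 1:3]
      }
    }
    return(raster_image(px))
  }
  if (length(magic) >= 2L &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) {
    return(raster_image(read_tiff_baseline(path)))
  }
  stop("unsupported image format (expected PNG or TIFF): ", path)
}

#' Write a PNG or TIFF image
#'
#' The output format follows the file extension (`.png`, `.tif`, `.tiff`).
#'
#' @param img A `raster_image` or coercible matrix/array, 8-bit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_raster_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unclass(img) / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff_baseline(unclass(img), path)
  } else {
    stop("unsupported output extension '.", ext, "' (use png or tiff)")
  }
  invisible(path)
}

#' Convert an image to grayscale
#'
#' RGB images are converted with BT.601 luma weights
#' (0.299, 0.587, 0.114), rounded half-up to integers. A grayscale input is
#' returned unchanged (idempotent).
#'
#' @param img A `raster_image` (1 or 3 channels).
#' @return A single-channel `raster_image` of the same size.
#' @export
to_grayscale <- function(img) {
  img <- as_raster_image(img, float = TRUE)
  if (img_channels(img) == 1L) return(img)
  px <- unclass(img)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  raster_image(floor(g + 0.5))
}

#' Axis-aligned pixel box
#'
#' Half-open box: rows `top .. top+height-1`, cols `left .. left+width-1`,
#' 0-based.
#'
#' @param top,left 0-based row/col of the top-left pixel.
#' @param height,width Extent in pixels (>= 1).
#' @return A `pixel_box` list.
#' @export
pixel_box <- function(top, left, height, width) {
  stopifnot(top >= 0, left >= 0, height >= 1, width >= 1)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "pixel_box")
}

check_box_inside <- function(box, img) {
  M <- img_height(img); N <- img_width(img)
  if (box$top + box$height > M || box$left + box$width > N)
    stop(sprintf("box (%d,%d,%dx%d) extends outside the %d x %d image",
                 box$top, box$left, box$height, box$width, M, N))
  invisible(TRUE)
}

#' Burn box outlines into a copy of an image
#'
#' Draws 1-px-wide rectangle outlines; the input is not modified. On RGB
#' images the outline is red by default, on grayscale it is white.
#'
#' @param img A `raster_image`.
#' @param boxes A list of [pixel_box()] (a single box is accepted).
#' @param colour Outline intensity: length-3 RGB for colour images or a
#'   single gray level. Defaults: `c(255, 0, 0)` / `255`.
#' @return Annotated copy of `img`.
#' @export
annotate_boxes <- function(img, boxes, colour = NULL) {
  img <- as_raster_image(img)
  if (inherits(boxes, "pixel_box")) boxes <- list(boxes)
  out <- unclass(img)
  rgb <- img_channels(img) == 3L
  if (is.null(colour)) colour <- if (rgb) c(255, 0, 0) else 255
  for (b in boxes) {
    check_box_inside(b, img)
    rows <- (b$top + 1L):(b$top + b$height)       # 1-based for indexing
    cols <- (b$left + 1L):(b$left + b$width)
    er <- c(rows[1], rows[length(rows)])
    ec <- c(cols[1], cols[length(cols)])
    if (rgb) {
      for (k in 1:3) {
        out[er, cols, k] <- colour[k]
        out[rows, ec, k] <- colour[k]
      }
    } else {
      out[er, cols] <- colour[1]
      out[rows, ec] <- colour[1]
    }
  }
  raster_image(out)
}
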