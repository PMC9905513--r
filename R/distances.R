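tiles_adjacent <- function(r1, c1, r2, c2) {
  (r1 == r2 & c1 == c2) |
  (abs(r1 - r2) + abs(c1 - c2) == 1)     # same tile or 4-edge-adjacent
}

#' Inter-crystal distance statistics for a colour pair
#'
#' For a pair of colour classes `(A, B)`, computes Euclidean distances (um)
#' between crystal centroids in the global mosaic frame.
#'
#' * `mode = "nearest"` (default): for every crystal of class A, the
#'   distance to its nearest *distinct* crystal of class B. Not symmetric in
#'   A and B in general.
#' * `mode = "all_pairs"`: every unordered distinct pair, symmetric in A and
#'   B.
#'
#' With `neighbourhood = TRUE` (default) candidates are restricted to the
#' crystal's own tile plus the four edge-adjacent tiles (left, right, above,
#' below), matching how neighbouring photographs are compared; crystals with
#' no candidate in that neighbourhood contribute no distance. The standard
#' deviation is the sample SD (0 when a single distance remains).
#'
#' @param crystals Global crystal data frame (`x_um`, `y_um`, `colour`, and
#'   tile indices when `neighbourhood` is used).
#' @param pair Character vector `c(classA, classB)`; a single name means
#'   same-colour.
#' @param mode `"nearest"` or `"all_pairs"`.
#' @param neighbourhood Restrict to 4-adjacent tiles (`TRUE`) or use the
#'   whole field (`FALSE`).
#' @return A `distance_pair_stats` list: `pair`, `mode`, `distances_um`,
#'   `mean_um`, `sd_um`, `n`, `histogram` (filled by
#'   [distance_histogram()]).
#' @export
pair_distances <- function(crystals, pair, mode = c("nearest", "all_pairs"),
                           neighbourhood = TRUE) {
  mode <- match.arg(mode)
  if (length(pair) == 1L) pair <- c(pair, pair)
  same_class <- pair[1] == pair[2]
  a <- crystals[crystals$colour == pair[1], , drop = FALSE]
  b <- crystals[crystals$colour == pair[2], , drop = FALSE]
  insufficient <- if (same_class) nrow(a) < 2 else nrow(a) < 1 || nrow(b) < 1
  if (insufficient)
    stop(sprintf("insufficient data for pair (%s, %s): need %s",
                 pair[1], pair[2],
                 if (same_class) ">= 2 crystals" else ">= 1 crystal of each"))
  if (neighbourhood && (anyNA(a$tile_row) || anyNA(b$tile_row)))
    stop("neighbourhood mode requires tile indices; use neighbourhood = FALSE")

  dx <- outer(a$x_um, b$x_um, `-`)
  dy <- outer(a$y_um, b$y_um, `-`)
  D <- sqrt(dx^2 + dy^2)
  if (same_class) {
    diag(D) <- Inf                         # a and b are the same rows
  }
  if (neighbourhood) {
    adj <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      tiles_adjacent(a$tile_row[i], a$tile_col[i], b$tile_row[j], b$tile_col[j]))
    D[!adj] <- Inf
  }
  if (mode == "nearest") {
    d <- apply(D, 1L, min)
    d <- d[is.finite(d)]
  } else {
    if (same_class) D[lower.tri(D, diag = TRUE)] <- Inf   # unordered pairs once
    d <- D[is.finite(D)]
  }
  if (length(d) == 0)
    stop(sprintf("insufficient data for pair (%s, %s): no candidate within the tile neighbourhood",
                 pair[1], pair[2]))
  structure(list(pair = pair, mode = mode, distances_um = unname(d),
                 mean_um = mean(d),
                 sd_um = if (length(d) > 1) stats::sd(d) else 0,
                 n = length(d), histogram = NULL),
            class = "distance_pair_stats")
}

#' @export
print.distance_pair_stats <- function(x, ...) {
  cat(sprintf("<distance_pair_stats %s-%s (%s): n = %d, mean %.1f um, sd %.1f um>\n",
              x$pair[1], x$pair[2], x$mode, x$n, x$mean_um, x$sd_um))
  invisible(x)
}

#' Histogram of inter-crystal distances
#'
#' Equal-width bins, half-open `[e_k, e_{k+1})` with the last bin closed,
#' so counts always sum to `n`. Default: 10 bins over `[0, max distance]`.
#'
#' @param stats A `distance_pair_stats`.
#' @param bins Bin count, or an explicit vector of bin edges.
#' @return The `stats` object with its `histogram` field set to
#'   `list(edges, counts)`.
#' @export
distance_histogram <- function(stats, bins = 10) {
  stopifnot(inherits(stats, "distance_pair_stats"))
  d <- stats$distances_um
  if (length(d) == 0) stop("insufficient data: no distances to bin")
  if (length(bins) == 1L) {
    stopifnot(bins >= 1)
    hi <- max(d)
    if (hi == 0) hi <- 1                 # all-zero distances: single bin [0,1)
    edges <- seq(0, hi, length.out = bins + 1L)
  } else {
    edges <- sort(bins)
    if (min(d) < edges[1] || max(d) > edges[length(edges)])
      stop("explicit bin edges do not cover the distances")
  }
  k <- length(edges) - 1L
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = k)
  stats$histogram <- list(edges = edges, counts = counts)
  stats
}

#' Crystal density report
#'
#' @param crystals Global crystal data frame.
#' @param colour Class to count.
#' @param area_um2 Analyzed area in um^2 (> 0).
#' @return A `density_report` list: `colour`, `count`, `area_um2`,
#'   `density` (crystals per um^2).
#' @export
crystal_density <- function(crystals, colour, area_um2) {
  stopifnot(area_um2 > 0)
  count <- sum(crystals$colour == colour)
  structure(list(colour = colour, count = count, area_um2 = area_um2,
                 density = count / area_um2),
            class = "density_report")
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("<density_report %s: %d crystals / %g um^2 = %g per um^2>\n",
              x$colour, x$count, x$area_um2, x$density))
  invisible(x)
}
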