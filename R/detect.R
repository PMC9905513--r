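# 8-connected component labelling of a logical matrix. Returns an integer
# vector of component ids parallel to `coords` (the which() order of TRUE
# pixels). Delegated to igraph: pixels are vertices, 8-neighbour contacts
# are edges.
label_components <- function(mask) {
  coords <- which(mask, arr.ind = TRUE)
  k <- nrow(coords)
  if (k == 0L)
    return(list(coords = coords, membership = integer(0), n = 0L))
  key <- (coords[, 1] - 1) * ncol(mask) + coords[, 2]   # unique pixel key
  idx_of <- seq_len(k)
  names(idx_of) <- as.character(key)
  edges <- NULL
  # half the 8-neighbourhood; the other half is covered by symmetry
  for (off in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    nb_key <- (coords[, 1] - 1 + off[1]) * ncol(mask) + coords[, 2] + off[2]
    valid <- coords[, 1] + off[1] >= 1 & coords[, 1] + off[1] <= nrow(mask) &
             coords[, 2] + off[2] >= 1 & coords[, 2] + off[2] <= ncol(mask)
    j <- idx_of[as.character(nb_key)]
    keep <- valid & !is.na(j)
    if (any(keep)) edges <- rbind(edges, cbind(idx_of[keep], j[keep]))
  }
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  list(coords = coords, membership = comp$membership, n = comp$no)
}

#' Threshold a correlation map into detections
#'
#' Marks every map pixel strictly above `threshold` (flagged zero-variance
#' windows never fire). In `"raw"` mode each above-threshold pixel becomes a
#' detection; in `"grouped"` mode (default) 8-connected components of
#' above-threshold pixels are merged into one detection each, anchored at the
#' component's maximum-score pixel (ties broken toward the smallest
#' `(row, col)`). Each detection carries a template-sized box and the grid
#' reference of the box centre.
#'
#' @param cmap A [correlation_map()].
#' @param threshold Score threshold in `(-1, 1]`.
#' @param grouping `"grouped"` or `"raw"`.
#' @param grid [grid_config()] used for grid labels.
#' @return A `detection_set`: a data frame with columns `template_id`,
#'   `anchor_row`, `anchor_col` (0-based), `height`, `width`, `score`,
#'   `grid_label`, plus attributes `threshold` and `grouping`. An empty set
#'   is valid.
#' @export
detect <- function(cmap, threshold, grouping = c("grouped", "raw"),
                   grid = grid_config()) {
  stopifnot(inherits(cmap, "correlation_map"))
  grouping <- match.arg(grouping)
  if (threshold <= -1 || threshold > 1)
    stop("threshold must lie in (-1, 1]")
  mask <- cmap$values > threshold & !cmap$flat
  m <- cmap$template_dims[1]; n <- cmap$template_dims[2]
  M <- cmap$scene_dims[1]; N <- cmap$scene_dims[2]

  lab <- label_components(mask)
  if (lab$n == 0L) {
    out <- data.frame(template_id = character(0), anchor_row = integer(0),
                      anchor_col = integer(0), height = integer(0),
                      width = integer(0), score = numeric(0),
                      grid_label = character(0), stringsAsFactors = FALSE)
    return(new_detection_set(out, threshold, grouping))
  }
  coords <- lab$coords
  if (grouping == "raw") {
    anchors <- coords
    scores <- cmap$values[coords]
  } else {
    anchors <- matrix(0L, lab$n, 2L)
    scores <- numeric(lab$n)
    vals <- cmap$values[coords]
    for (g in seq_len(lab$n)) {
      px <- which(lab$membership == g)
      best <- max(vals[px])
      cand <- px[vals[px] >= best - 0]        # exact ties
      cand_rc <- coords[cand, , drop = FALSE]
      o <- order(cand_rc[, 1], cand_rc[, 2])[1]
      anchors[g, ] <- cand_rc[o, ]
      scores[g] <- best
    }
  }
  anchor_row <- anchors[, 1] - 1L                       # back to 0-based
  anchor_col <- anchors[, 2] - 1L
  centre_row <- pmin(anchor_row + m %/% 2L, M - 1L)
  centre_col <- pmin(anchor_col + n %/% 2L, N - 1L)
  labels <- vapply(seq_along(anchor_row), function(i)
    pixel_to_gridref(centre_row[i], centre_col[i], M, N, grid)$label, "")
  out <- data.frame(template_id = cmap$template_id,
                    anchor_row = anchor_row, anchor_col = anchor_col,
                    height = m, width = n, score = scores,
                    grid_label = labels, stringsAsFactors = FALSE)
  o <- order(out$anchor_row, out$anchor_col)
  new_detection_set(out[o, , drop = FALSE], threshold, grouping)
}

new_detection_set <- function(df, threshold, grouping) {
  rownames(df) <- NULL
  structure(df, threshold = threshold, grouping = grouping,
            class = c("detection_set", "data.frame"))
}

#' Count grouped detections across a range of thresholds
#'
#' @param cmap A [correlation_map()], or a list of them (counts are summed,
#'   matching the pooled "areas across all templates" reading).
#' @param t_lo,t_hi,step Sweep bounds and step; defaults 0.40-0.95 by 0.01.
#' @param grouping Counting mode, `"grouped"` (default) or `"raw"`.
#' @return Data frame `(threshold, n_detections)` ordered by descending
#'   threshold.
#' @export
sweep_thresholds <- function(cmap, t_lo = 0.40, t_hi = 0.95, step = 0.01,
                             grouping = c("grouped", "raw")) {
  stopifnot(t_lo < t_hi, step > 0)
  grouping <- match.arg(grouping)
  maps <- if (inherits(cmap, "correlation_map")) list(cmap) else cmap
  thresholds <- rev(seq(t_lo, t_hi, by = step))
  counts <- vapply(thresholds, function(t)
    sum(vapply(maps, function(cm) nrow(detect(cm, t, grouping)), 0L)), 0L)
  data.frame(threshold = thresholds, n_detections = counts)
}

#' Pick the working threshold from a sweep
#'
#' Scans the sweep for the knee where the detection count "increases
#' drastically" as the threshold is lowered: returns the lowest threshold
#' `t` whose next-lower neighbour multiplies the count by at least
#' `jump_factor` — the last stable value before the blow-up. The factor
#' defaults to 6, the jump observed below the useful range on the original
#' survey. If no jump exists the sweep is flat-ish; the midpoint of the
#' swept range is returned with a warning.
#'
#' @param sweep Data frame from [sweep_thresholds()].
#' @param jump_factor Count ratio treated as "drastic" (> 1).
#' @return Selected threshold (scalar).
#' @export
select_threshold <- function(sweep, jump_factor = 6) {
  stopifnot(nrow(sweep) >= 1, jump_factor > 1)
  sweep <- sweep[order(-sweep$threshold), , drop = FALSE]
  if (all(sweep$n_detections == 0))
    stop("no detections at any swept threshold")
  n <- nrow(sweep)
  if (n >= 2) {
    ratio <- sweep$n_detections[-1] / pmax(sweep$n_detections[-n], 1)
    jumps <- which(ratio >= jump_factor)
    if (length(jumps) > 0)
      return(sweep$threshold[max(jumps)])   # lowest threshold with a jump
  }
  mid <- (max(sweep$threshold) + min(sweep$threshold)) / 2
  warning(sprintf(
    "no count jump >= factor %.3g found in sweep; returning range midpoint %.4g",
    jump_factor, mid))
  mid
}

#' Sampling-efficiency report
#'
#' Efficiency of the detector as a sampling guide: the percentage of
#' software-detected areas whose physical sampling returned microbial
#' growth, `100 * n_positive / n_detected`. The survey that motivated the
#' score detected 18 possible areas of which 2 sampled positive: 11%.
#'
#' @param n_detected Total detected areas across all templates (>= 1).
#' @param n_positive Areas with positive microbial growth (>= 0).
#' @param n_sampled Areas actually swabbed (optional; sampling can cover
#'   areas beyond software hits, so no ordering against `n_detected` is
#'   enforced — only `n_positive <= n_sampled`).
#' @return An `efficiency_report` list: `n_detected`, `n_sampled`,
#'   `n_positive`, `efficiency` (unrounded percent), `efficiency_pct`
#'   (rounded to nearest integer percent).
#' @export
efficiency <- function(n_detected, n_positive, n_sampled = NA_integer_) {
  if (length(n_detected) != 1 || is.na(n_detected) || n_detected < 1)
    stop("efficiency undefined: n_detected must be >= 1")
  stopifnot(n_positive >= 0)
  if (!is.na(n_sampled) && n_positive > n_sampled)
    stop("n_positive cannot exceed n_sampled")
  eff <- 100 * n_positive / n_detected
  structure(list(n_detected = as.integer(n_detected),
                 n_sampled = as.integer(n_sampled),
                 n_positive = as.integer(n_positive),
                 efficiency = eff,
                 efficiency_pct = as.integer(floor(eff + 0.5))),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Sampling efficiency: %d%% (%.2f%% unrounded; %d positive / %d detected)\n",
              x$efficiency_pct, x$efficiency, x$n_positive, x$n_detected))
  invisible(x)
}

#' End-to-end detection run
#'
#' Grayscale conversion, one correlation map per template, thresholding,
#' grouped detections with grid labels, pooled counts, and (optionally) a
#' box-annotated overlay and a CSV report. Deterministic: identical inputs
#' produce byte-identical outputs.
#'
#' @param scene Scene image: a file path or a `raster_image`.
#' @param templates Template images: file paths or `raster_image`s /
#'   matrices (named list; names become template ids).
#' @param threshold Fixed threshold, or `"sweep"` to select one per
#'   template with [sweep_thresholds()] + [select_threshold()]. Default
#'   0.675, the midpoint of the useful 0.65-0.70 range.
#' @param grouping Passed to [detect()].
#' @param grid [grid_config()].
#' @param report_csv,overlay_png Optional output paths.
#' @param jump_factor Passed to [select_threshold()] when sweeping.
#' @return A `detection_set` pooled over templates, with attribute
#'   `thresholds` (named per template).
#' @export
run_detection <- function(scene, templates, threshold = 0.675,
                          grouping = "grouped", grid = grid_config(),
                          report_csv = NULL, overlay_png = NULL,
                          jump_factor = 6) {
  scene_img <- if (is.character(scene)) read_image(scene) else as_raster_image(scene)
  gray <- to_grayscale(scene_img)
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  sets <- list(); thr_used <- numeric(0)
  for (id in names(templates)) {
    tp <- templates[[id]]
    timg <- if (is.character(tp)) read_image(tp) else as_raster_image(tp, float = TRUE)
    tmpl <- template_pattern(to_grayscale(timg), template_id = id)
    cm <- correlation_map(gray, tmpl)
    t_use <- if (identical(threshold, "sweep"))
      select_threshold(sweep_thresholds(cm), jump_factor) else threshold
    thr_used[id] <- t_use
    sets[[id]] <- detect(cm, t_use, grouping, grid)
  }
  pooled <- do.call(rbind, lapply(sets, as.data.frame))
  pooled <- pooled[order(pooled$template_id, pooled$anchor_row, pooled$anchor_col),
                   , drop = FALSE]
  rownames(pooled) <- NULL
  out <- structure(pooled, thresholds = thr_used,
                   threshold = unname(thr_used[1]), grouping = grouping,
                   class = c("detection_set", "data.frame"))
  if (!is.null(report_csv))
    utils::write.csv(as.data.frame(out), report_csv, row.names = FALSE)
  if (!is.null(overlay_png)) {
    boxes <- lapply(seq_len(nrow(pooled)), function(i)
      pixel_box(pooled$anchor_row[i], pooled$anchor_col[i],
                pooled$height[i], pooled$width[i]))
    write_image(annotate_boxes(scene_img, boxes), overlay_png)
  }
  out
}
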