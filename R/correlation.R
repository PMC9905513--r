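#' Template pattern
#'
#' A grayscale template (matrix R, m x n) with its mean intensity cached.
#' Matching requires a non-constant template (variance > 0).
#'
#' @param gray Grayscale matrix or `raster_image` (coerced with
#'   [to_grayscale()] if RGB).
#' @param template_id Identifier carried into detections and reports.
#' @return A `template_pattern` object with fields `gray`, `mean`,
#'   `template_id`.
#' @export
template_pattern <- function(gray, template_id = "template") {
  if (inherits(gray, "raster_image") || length(dim(gray)) == 3L)
    gray <- to_grayscale(as_raster_image(gray, float = TRUE))
  gray <- unclass(gray)
  stopifnot(is.matrix(gray), nrow(gray) >= 1, ncol(gray) >= 1)
  if (stats::var(as.vector(gray)) == 0)
    stop("degenerate template: constant intensity has no pattern to match")
  structure(list(gray = gray, mean = mean(gray), template_id = template_id),
            class = "template_pattern")
}

# Per-window sums over all m x n windows of X, via a zero-padded summed-area
# table. Returns the (M-m+1) x (N-n+1) matrix of window sums.
window_sums <- function(X, m, n) {
  M <- nrow(X); N <- ncol(X)
  colcum <- function(A) if (nrow(A) == 1L) A else apply(A, 2L, cumsum)
  rowcum <- function(A) if (ncol(A) == 1L) A else t(apply(A, 1L, cumsum))
  S <- matrix(0, M + 1L, N + 1L)
  S[-1L, -1L] <- rowcum(colcum(X))
  rows <- 1L:(M - m + 1L); cols <- 1L:(N - n + 1L)
  S[rows + m, cols + n, drop = FALSE] - S[rows, cols + n, drop = FALSE] -
    S[rows + m, cols, drop = FALSE] + S[rows, cols, drop = FALSE]
}

# Valid-mode cross-correlation sum_{i,j} X[r+i, s+j] * K[i, j] via 2-D FFT.
valid_crosscorr <- function(X, K) {
  M <- nrow(X); N <- ncol(X)
  m <- nrow(K); n <- ncol(K)
  Kp <- matrix(0, M, N)
  Kp[1:m, 1:n] <- K
  cc <- Re(stats::fft(stats::fft(X) * Conj(stats::fft(Kp)), inverse = TRUE)) / (M * N)
  cc[1:(M - m + 1L), 1:(N - n + 1L), drop = FALSE]
}

#' Correlation-coefficient map of a template over a scene
#'
#' Slides the template R (m x n) over every same-size window of the scene I
#' (M x N) and scores each window with the normalized correlation
#' coefficient
#' \deqn{C(r,s) = \frac{\sum_{i,j} (I(i+r, j+s) - \bar I_{rs}) (R(i,j) - \bar R)}
#'                    {\sqrt{\sum_{i,j}(I(i+r,j+s)-\bar I_{rs})^2 \;
#'                           \sum_{i,j}(R(i,j)-\bar R)^2}},}
#' where \eqn{\bar I_{rs}} is the mean of the window, so scores lie in
#' \eqn{[-1, +1]} and are invariant to affine intensity changes of the scene
#' (uneven lighting, local brightness/contrast shifts). Valid mode only: the
#' map has dimensions \eqn{(M-m+1) \times (N-n+1)}. Windows with (numerically)
#' zero variance carry no pattern evidence; they score 0 and are flagged.
#'
#' The implementation uses a 2-D FFT for the numerator and summed-area
#' tables for the window means/variances; it is algebraically identical to
#' the direct double loop over windows.
#'
#' @param scene Grayscale scene (`raster_image`, matrix; RGB inputs are
#'   converted).
#' @param template A [template_pattern()] (matrices are coerced).
#' @return A `correlation_map` with fields `values` (the map), `flat`
#'   (logical matrix flagging zero-variance windows), `scene_dims`,
#'   `template_dims`, `template_id`.
#' @export
correlation_map <- function(scene, template) {
  if (!inherits(template, "template_pattern")) template <- template_pattern(template)
  if (inherits(scene, "raster_image") || length(dim(scene)) == 3L)
    scene <- to_grayscale(as_raster_image(scene, float = TRUE))
  I <- unclass(scene)
  stopifnot(is.matrix(I))
  R <- template$gray
  M <- nrow(I); N <- ncol(I); m <- nrow(R); n <- ncol(R)
  if (m > M || n > N)
    stop(sprintf("template (%d x %d) larger than scene (%d x %d)", m, n, M, N))

  I0 <- I - mean(I)                      # global shift; cancels in C, tames fp
  R0 <- R - mean(R)
  ss_R <- sum(R0^2)
  mn <- m * n

  num <- valid_crosscorr(I0, R0)         # window mean cancels: sum(R0) == 0
  W1 <- window_sums(I0, m, n)
  W2 <- window_sums(I0 * I0, m, n)
  ss_w <- pmax(W2 - W1 * W1 / mn, 0)     # per-window sum of squared deviations

  flat <- ss_w <= 1e-6 * mn              # window sd <= 1e-3 intensity units
  denom <- sqrt(ss_w * ss_R)
  vals <- num / ifelse(flat, 1, denom)
  vals[flat] <- 0
  structure(list(values = vals, flat = flat,
                 scene_dims = c(M, N), template_dims = c(m, n),
                 template_id = template$template_id),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf(
    "<correlation_map %d x %d (scene %d x %d, template '%s' %d x %d), max %.4f>\n",
    nrow(x$values), ncol(x$values), x$scene_dims[1], x$scene_dims[2],
    x$template_id, x$template_dims[1], x$template_dims[2], max(x$values)))
  invisible(x)
}
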