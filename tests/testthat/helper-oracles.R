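# Independent oracles and fixture builders shared across test files.
# The correlation oracle is a literal transcription of the defining
# equations (double loop over windows, per-window mean), kept free of any
# production code path.

oracle_correlation_map <- function(I, R) {
  M <- nrow(I); N <- ncol(I); m <- nrow(R); n <- ncol(R)
  Rbar <- mean(R)
  C <- matrix(0, M - m + 1, N - n + 1)
  for (r in seq_len(M - m + 1)) {
    for (s in seq_len(N - n + 1)) {
      W <- I[r:(r + m - 1), s:(s + n - 1)]
      Ibar <- mean(W)
      Z <- sqrt(sum((W - Ibar)^2) * sum((R - Rbar)^2))
      C[r, s] <- if (Z > 0) sum((W - Ibar) * (R - Rbar)) / Z else 0
    }
  }
  C
}

# A degraded plant whose window correlation with `tmpl` is exactly `rho`
# (up to 8-bit quantization): Gram-Schmidt mixture of the template with a
# rough pattern orthogonalized against it.
make_degraded_patch <- function(tmpl, rho, bg = 128) {
  T0 <- unclass(tmpl) - mean(unclass(tmpl))
  nT <- sqrt(sum(T0^2))
  Q0 <- matrix(stats::runif(length(T0), -1, 1), nrow(T0))
  Q0 <- Q0 - mean(Q0)
  Q1 <- Q0 - sum(Q0 * T0) / sum(T0^2) * T0
  P0 <- rho * T0 / nT + sqrt(1 - rho^2) * Q1 / sqrt(sum(Q1^2))
  floor(pmin(pmax(bg + 0.8 * nT * P0, 0), 255) + 0.5)
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# crystal data frame shorthand for distance tests
crystal_df <- function(x, y, colour = "blue", tile_row = 1L, tile_col = 1L) {
  data.frame(x_um = x, y_um = y, colour = rep_len(colour, length(x)),
             tile_row = rep_len(tile_row, length(x)),
             tile_col = rep_len(tile_col, length(x)),
             stringsAsFactors = FALSE)
}
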