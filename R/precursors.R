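#' Classical time-series precursors: volatility spectral radius
#'
#' Baseline early-warning statistic from the critical-slowing-down
#' literature: at each step `t >= W + 1`, the spectral radius of the sample
#' covariance matrix of one-step state increments over the trailing window
#' of length `W`.  Used as a contrast for the quantization signal, which
#' anticipates structural collapse while volatility-based statistics react
#' only after it.
#'
#' @param series numeric matrix, one row per step, one column per node.
#' @param window trailing window length `W` (number of increments).
#' @return numeric vector, one entry per step; `NA` for steps `<= W`.
#' @export
volatility_spectral_radius <- function(series, window = 50) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  if (Tn < window + 1) stop("series shorter than window + 1")
  D <- diff(series)
  out <- rep(NA_real_, Tn)
  for (t in (window + 1):Tn) {
    Cv <- cov(D[(t - window):(t - 1), , drop = FALSE])
    out[t] <- max(abs(eigen(Cv, symmetric = TRUE, only.values = TRUE)$values))
  }
  out
}

#' Classical time-series precursors: lagged cross-correlation spectral radius
#'
#' At each step, the spectral radius of the lag-`lag` Pearson
#' cross-correlation matrix `C_ij = cor(x_i(s), x_j(s + lag))` estimated
#' over the trailing window.  Node pairs involving a zero-variance node in
#' the window get correlation 0; the affected steps are flagged in the
#' `"degenerate"` attribute.
#'
#' @inheritParams volatility_spectral_radius
#' @param lag cross-correlation lag (default 1; 0 gives the ordinary
#'   correlation matrix).
#' @return numeric vector per step (`NA` for steps `< window + lag`), with
#'   attribute `"degenerate"`: logical per step, `TRUE` where zero-variance
#'   nodes were zeroed out.
#' @export
crosscorr_spectral_radius <- function(series, window = 50, lag = 1) {
  series <- as.matrix(series)
  Tn <- nrow(series)
  stopifnot(lag >= 0)
  if (Tn < window + lag) stop("series shorter than window + lag")
  out <- rep(NA_real_, Tn)
  degen <- rep(FALSE, Tn)
  for (t in (window + lag):Tn) {
    s0 <- (t - window - lag + 1):(t - lag)
    X <- series[s0, , drop = FALSE]
    Y <- series[s0 + lag, , drop = FALSE]
    sx <- apply(X, 2, sd)
    sy <- apply(Y, 2, sd)
    ok_x <- sx > 0
    ok_y <- sy > 0
    Cm <- matrix(0, ncol(series), ncol(series))
    if (any(ok_x) && any(ok_y)) {
      Cm[ok_x, ok_y] <- suppressWarnings(
        cor(X[, ok_x, drop = FALSE], Y[, ok_y, drop = FALSE]))
      Cm[is.na(Cm)] <- 0
    }
    degen[t] <- !all(ok_x & ok_y)
    out[t] <- max(Mod(eigen(Cm, only.values = TRUE)$values))
  }
  attr(out, "degenerate") <- degen
  out
}
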