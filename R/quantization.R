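#' Detect integer quantization of a state vector
#'
#' Tests whether every component of a normalized state vector is an integer
#' multiple of its minimal non-zero component `x_min`.  For a linear
#' catalytic system whose network holds exactly one simple directed cycle,
#' the attractor always has this property, with the integer levels equal to
#' the number of directed paths from the cycle to each node; detecting the
#' quantization therefore flags the last surviving cycle -- and imminent
#' structural collapse -- from node states alone.
#'
#' The detector is scale invariant: the input is renormalized internally, so
#' `x` and `a * x` produce identical reports.
#'
#' @param x numeric state vector (or an [attractor()] result, whose `$x` is
#'   used).
#' @param rel_tol maximal tolerated deviation of `x_i / x_min` from the
#'   nearest integer (default `1e-6`, appropriate for exact linear
#'   attractors; use a loose value such as `0.15` for noisy empirical
#'   estimates).
#' @param zero_tol support threshold; entries at or below it count as zero.
#'   Default `1e-9 * max(x)` -- numerically-zero attractor components are
#'   only approximately zero.
#' @return list of class `quantization_report`: `is_quantized`, `x_min`,
#'   `levels` (integer `n_i`, 0 off-support), `max_deviation`, `zero_threshold`.
#' @examples
#' detect_quantization(c(0.2, 0.2, 0.2, 0.4))$levels  # 1 1 1 2
#' @export
detect_quantization <- function(x, rel_tol = 1e-6, zero_tol = NULL) {
  if (inherits(x, "attractor_result")) x <- x$x
  x <- as.numeric(x)
  stopifnot(rel_tol > 0, all(x >= 0))
  if (sum(x) <= 0) stop("degenerate input: state vector has no mass")
  x <- x / sum(x)
  if (is.null(zero_tol)) zero_tol <- 1e-9 * max(x)
  support <- x > zero_tol
  if (!any(support)) stop("degenerate input: all entries below zero_tol")
  x_min <- min(x[support])
  ratios <- x[support] / x_min
  lev <- as.integer(round(ratios))
  dev <- max(abs(ratios - lev))
  levels <- integer(length(x))
  levels[support] <- lev
  is_q <- dev <= rel_tol && all(lev >= 1L)
  structure(list(is_quantized = is_q, x_min = x_min, levels = levels,
                 max_deviation = dev, zero_threshold = zero_tol),
            class = "quantization_report")
}

#' @export
print.quantization_report <- function(x, ...) {
  cat(sprintf("quantization: %s (x_min = %.4g, max deviation = %.3g)\n",
              if (x$is_quantized) "DETECTED" else "absent",
              x$x_min, x$max_deviation))
  invisible(x)
}

#' Detect logarithmic quantization
#'
#' Tests whether the logarithms of a strictly positive state vector sit on
#' an equispaced integer ladder `log(x_i / min x) = k_i * delta`, the
#' signature of a single weighted reproduction cycle such as the Leslie
#' population model with one reproductive stage: there
#' `log x` is proportional to `(N-1, N-2, ..., 1, 0)` with spacing
#' `log(f/p) / N`.  The spacing is initialized as the minimal positive gap
#' among the sorted distinct log-values (consecutive levels are guaranteed
#' to occur in the Leslie case) and refined by least squares.
#'
#' @param x strictly positive state vector.
#' @param tol maximal tolerated deviation of `log(x_i / min x)` from
#'   `k_i * delta` (default `1e-6`).
#' @return list of class `log_quantization_report`: `is_quantized`, `delta`
#'   (common log spacing), `levels` (integer `k_i`), `max_deviation`.
#' @examples
#' detect_log_quantization(c(1, 2, 4, 8))$delta  # log(2)
#' @export
detect_log_quantization <- function(x, tol = 1e-6) {
  x <- as.numeric(x)
  if (any(x <= 0)) stop("log quantization needs strictly positive entries")
  stopifnot(tol > 0)
  l <- log(x / min(x))
  if (max(l) <= tol) {
    return(structure(list(is_quantized = TRUE, delta = 0,
                          levels = integer(length(x)), max_deviation = max(l)),
                     class = "log_quantization_report"))
  }
  ls <- sort(unique(l))
  gaps <- diff(ls)
  gaps <- gaps[gaps > tol]
  delta <- if (length(gaps)) min(gaps) else max(l)
  k <- round(l / delta)
  # least-squares refinement of the common spacing given the levels
  if (sum(k^2) > 0) delta <- sum(k * l) / sum(k^2)
  k <- round(l / delta)
  if (sum(k^2) > 0) delta <- sum(k * l) / sum(k^2)
  dev <- max(abs(l - k * delta))
  structure(list(is_quantized = dev <= tol, delta = delta,
                 levels = as.integer(k), max_deviation = dev),
            class = "log_quantization_report")
}

#' @export
print.log_quantization_report <- function(x, ...) {
  cat(sprintf("log quantization: %s (spacing = %.6g, max deviation = %.3g)\n",
              if (x$is_quantized) "DETECTED" else "absent",
              x$delta, x$max_deviation))
  invisible(x)
}

#' Early-warning signal over a state-vector series
#'
#' Applies [detect_quantization()] step by step: the signal is active
#' whenever the state vector quantizes -- the non-structural fingerprint of
#' a single remaining cycle.  Quantization can also occur spuriously when
#' the dominant eigenvalue is an integer larger than one; if a `lambda1`
#' series is available the optional guard suppresses activations with
#' `lambda1 > 1 + rel_tol`.  For sparse networks, where `lambda1` stays
#' close to one, the unguarded signal is already reliable.
#'
#' @param x_series list of state vectors, or a matrix with one row per step.
#' @param lambda1_series optional dominant eigenvalues, one per step.
#' @param lambda1_guard apply the `lambda1 <= 1 + rel_tol` guard when
#'   `lambda1_series` is given (default `TRUE`).
#' @inheritParams detect_quantization
#' @return list of class `warning_series`: `signal` (logical per step) and
#'   `onsets` (first step index of each contiguous active run).
#' @export
warning_signal <- function(x_series, lambda1_series = NULL,
                           rel_tol = 1e-6, zero_tol = NULL,
                           lambda1_guard = TRUE) {
  if (is.matrix(x_series))
    x_series <- lapply(seq_len(nrow(x_series)), function(i) x_series[i, ])
  stopifnot(length(x_series) >= 1)
  signal <- vapply(x_series, function(x)
    detect_quantization(x, rel_tol = rel_tol, zero_tol = zero_tol)$is_quantized,
    logical(1))
  if (lambda1_guard && !is.null(lambda1_series)) {
    stopifnot(length(lambda1_series) == length(signal))
    signal <- signal & (lambda1_series <= 1 + rel_tol)
  }
  runs <- rle(signal)
  starts <- cumsum(c(1L, head(runs$lengths, -1L)))
  structure(list(signal = signal, onsets = starts[runs$values]),
            class = "warning_series")
}

#' @export
print.warning_series <- function(x, ...) {
  cat(sprintf("warning signal: active at %d / %d steps (%d activation run(s))\n",
              sum(x$signal), length(x$signal), length(x$onsets)))
  invisible(x)
}
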