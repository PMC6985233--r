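#' Katz centrality
#'
#' Solves the linear system `x = alpha * M x + beta_k * 1` exactly.  Katz
#' centrality adds a uniform baseline `beta_k` to the eigenvector-centrality
#' recursion; as the attenuation `alpha` approaches `1 / lambda_1` the
#' direction of the Katz vector converges to the dominant eigenvector, so on
#' single-cycle networks (`lambda_1 = 1`) the integer quantization reappears
#' in the limit `alpha -> 1`.  At smaller `alpha` the levels shift off the
#' integers and split into sub-levels.
#'
#' @param net a [directed_network()] or [weighted_network()].
#' @param alpha attenuation factor, `0 < alpha < 1 / lambda_1` (strict; the
#'   system is singular at the bound, which is approached as a limit).
#' @param beta_k uniform baseline score (> 0).
#' @return positive numeric vector of Katz scores.
#' @examples
#' katz_centrality(cycle_network(3), alpha = 0.5)
#' @export
katz_centrality <- function(net, alpha, beta_k = 1) {
  stopifnot(alpha > 0, beta_k > 0)
  M <- as_influence_matrix(net)
  l1 <- dominant_eigenvalue(net)
  if (l1 > 0 && alpha >= 1 / l1)
    stop(sprintf("alpha must be < 1/lambda1 = %.6g (got %.6g)", 1 / l1, alpha))
  n <- nrow(M)
  as.numeric(solve(diag(1, n) - alpha * M, rep(beta_k, n)))
}

#' Randomly weight the links of a binary network
#'
#' Reweights every existing link independently by a uniform draw from
#' `[1 - epsilon, 1]`, keeping the topology fixed.  `epsilon = 0` recovers
#' the binary network; as `epsilon` grows the quantization signature of a
#' single-cycle network deteriorates gradually.
#'
#' @param net a [directed_network()].
#' @param epsilon noise amplitude in `[0, 1]`.
#' @return a [weighted_network()] with the same zero pattern.
#' @export
randomize_weights <- function(net, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  A <- unclass(as.matrix(net))
  W <- matrix(0, nrow(A), ncol(A))
  links <- which(A != 0)
  W[links] <- runif(length(links), min = 1 - epsilon, max = 1)
  weighted_network(W)
}

#' Leslie population-projection matrix
#'
#' Builds the stage-structured projection matrix of the discrete dynamics
#' `x_1(t+1) = sum_{j>1} f_j x_j(t)`, `x_j(t+1) = p_{j-1} x_{j-1}(t)`:
#' fecundities `f_j` on the first row, survival fractions on the
#' sub-diagonal.  With a single reproductive stage the matrix is a weighted
#' single-cycle network.
#'
#' @param fecundities numeric vector `f` (per stage; `f[1]` is ignored by
#'   the dynamics and must be 0 to keep the zero diagonal).
#' @param survivals numeric vector `p` of length `N - 1`, entries in (0, 1].
#' @return a [weighted_network()] of the `N x N` Leslie matrix.
#' @examples
#' leslie_matrix(c(0, 0, 2), c(0.5, 0.5))
#' @export
leslie_matrix <- function(fecundities, survivals) {
  N <- length(fecundities)
  stopifnot(N >= 2, length(survivals) == N - 1,
            all(fecundities >= 0), fecundities[1] == 0,
            all(survivals > 0), all(survivals <= 1))
  L <- matrix(0, N, N)
  L[1, ] <- fecundities
  L[cbind(2:N, 1:(N - 1))] <- survivals
  weighted_network(L)
}

#' Closed-form spectrum of the single-cycle Leslie model
#'
#' For a Leslie model whose only reproductive stage is the last one
#' (`f_N = f`, all other fecundities 0) and uniform survival `p`, the
#' projection matrix is a weighted `N`-cycle with
#' `lambda_1 = p * (f/p)^(1/N)` and dominant eigenvector
#' `x = ((f/p)^((N-1)/N), ..., (f/p)^(1/N), 1)`, so `log x` is an
#' equispaced ladder with spacing `log(f/p) / N` -- a logarithmic
#' quantization.
#'
#' @param f fecundity of the last stage (> 0).
#' @param p uniform survival fraction in (0, 1].
#' @param N number of stages (>= 2).
#' @return list of class `leslie_spectral`: `lambda1`, `x` (closed-form
#'   eigenvector, last entry 1), `log_levels` (`N-1, ..., 0`),
#'   `log_spacing` (`log(f/p)/N`), and `matrix` (the [leslie_matrix()]).
#' @examples
#' leslie_spectral(f = 2, p = 0.5, N = 3)$lambda1  # 0.5 * 4^(1/3)
#' @export
leslie_spectral <- function(f, p, N) {
  stopifnot(f > 0, p > 0, p <= 1, N >= 2)
  L <- leslie_matrix(c(rep(0, N - 1), f), rep(p, N - 1))
  lambda1 <- p * (f / p)^(1 / N)
  x <- (f / p)^((N - seq_len(N)) / N)
  structure(list(lambda1 = lambda1, x = x,
                 log_levels = (N - 1):0,
                 log_spacing = log(f / p) / N,
                 matrix = L),
            class = "leslie_spectral")
}

#' @export
print.leslie_spectral <- function(x, ...) {
  cat(sprintf("Leslie spectrum: N = %d, lambda1 = %.6g, log spacing = %.6g\n",
              length(x$x), x$lambda1, x$log_spacing))
  invisible(x)
}
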