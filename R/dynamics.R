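#' Integrate the linear catalytic dynamics
#'
#' Solves `dX_i/dt = sum_j M_ij X_j - phi * X_i` on a time grid via the
#' closed-form matrix exponential `X(t) = exp((M - phi I) t) X(0)`.  The
#' uniform depletion rate `phi` rescales all components by `exp(-phi t)` and
#' therefore cancels under normalization.
#'
#' @param net a [directed_network()] or [weighted_network()].
#' @param t_grid increasing nonnegative times, starting at 0.
#' @param phi uniform depletion/decay rate (>= 0).
#' @param x0 strictly positive initial state vector, or `"uniform"`.
#' @return matrix with one row per grid time and one column per node
#'   (raw, unnormalized states).
#' @examples
#' net <- cycle_network(3)
#' X <- integrate_states(net, t_grid = c(0, 1, 5))
#' @export
integrate_states <- function(net, t_grid, phi = 0, x0 = "uniform") {
  M <- as_influence_matrix(net)
  n <- nrow(M)
  x0 <- resolve_x0(x0, n)
  stopifnot(length(t_grid) >= 1, t_grid[1] == 0, !is.unsorted(t_grid),
            all(t_grid >= 0), phi >= 0)
  G <- M - diag(phi, n)
  out <- matrix(NA_real_, length(t_grid), n)
  for (k in seq_along(t_grid)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(G * t_grid[k])))
    out[k, ] <- as.numeric(E %*% x0)
  }
  out
}

resolve_x0 <- function(x0, n) {
  if (identical(x0, "uniform")) return(rep(1 / n, n))
  x0 <- as.numeric(x0)
  if (length(x0) != n) stop("x0 has wrong length")
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  x0
}

#' Normalized attractor of the linear dynamics
#'
#' Computes the long-time limit of the normalized state
#' `x_i = X_i / sum_j X_j` by power iteration on `I + M`, accelerated by
#' repeated squaring with max-renormalization.  The shift makes the dominant
#' eigenvalue of the iteration matrix real and strictly dominant whenever
#' the network carries a cycle (the cycle eigenvalues on the circle
#' `|lambda| = lambda_1` are separated by the shift), and for acyclic
#' (nilpotent) networks the iteration converges to the direction of
#' `M^k x0` at the nilpotency index -- the matrix-exponential limit, whose
#' support sits at the ends of maximal chains.  The limit satisfies the
#' eigenvalue relation `lambda_1 x = M x`.
#'
#' The result does not depend on `phi` (uniform decay cancels under
#' normalization), which is accepted for interface symmetry with
#' [integrate_states()].
#'
#' @inheritParams integrate_states
#' @param tol convergence tolerance on the max-norm change of the
#'   normalized iterate (default `1e-12`).
#' @param max_iter cap on the effective power `(I + M)^k` (default `1e6`).
#' @return list of class `attractor_result`: `x` (normalized, sums to 1),
#'   `lambda1` (Rayleigh estimate of the dominant eigenvalue at the limit),
#'   `residual` (max-norm of `lambda1 * x - M x`), `converged`,
#'   `iterations` (effective power applied).
#' @examples
#' attractor(cycle_network(2))$x  # 0.5 0.5
#' @export
attractor <- function(net, phi = 0, x0 = "uniform",
                      tol = 1e-12, max_iter = 1e6) {
  M <- as_influence_matrix(net)
  n <- nrow(M)
  x0 <- resolve_x0(x0, n)

  Ab <- matrix(as.integer(M != 0), n, n)
  if (!cpp_cycle_flags(Ab)$has_cycle) {
    # nilpotent generator: the normalized matrix-exponential limit is the
    # direction of M^k x0 at the last non-vanishing power k (chain ends)
    y <- x0
    k <- 0
    repeat {
      z <- as.numeric(M %*% y)
      if (max(abs(z)) == 0) break
      y <- z / max(z)
      k <- k + 1
    }
    x <- y / sum(y)
    return(structure(list(x = x, lambda1 = 0,
                          residual = max(abs(as.numeric(M %*% x))),
                          converged = TRUE, iterations = k),
                     class = "attractor_result"))
  }

  B <- M + diag(1, n)
  P <- B
  power <- 1
  x_prev <- x0 / sum(x0)
  converged <- FALSE
  while (power < max_iter) {
    P <- P %*% P
    P <- P / max(P)            # diagonal of B is 1, so max(P) >= 1 always
    power <- power * 2
    x <- as.numeric(P %*% x0)
    x <- x / sum(x)
    if (max(abs(x - x_prev)) <= tol) {
      converged <- TRUE
      x_prev <- x
      break
    }
    x_prev <- x
  }
  x <- x_prev
  Mx <- as.numeric(M %*% x)
  lambda1 <- sum(x * Mx) / sum(x * x)
  if (lambda1 < tol) lambda1 <- 0
  residual <- max(abs(lambda1 * x - Mx))
  structure(list(x = x, lambda1 = lambda1, residual = residual,
                 converged = converged, iterations = power),
            class = "attractor_result")
}

#' @export
print.attractor_result <- function(x, ...) {
  cat(sprintf(
    "attractor: lambda1 = %.6g, residual = %.3g, %sconverged (power %g)\n",
    x$lambda1, x$residual, if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' Dominant eigenvalue (spectral radius) of the influence matrix
#'
#' For binary networks the spectral radius is 0 iff the network is acyclic
#' (nilpotent matrix) and at least 1 otherwise; it equals exactly 1 whenever
#' the network contains a single simple directed cycle, the fact exploited
#' by the quantization-based warning signal.
#'
#' @param net a [directed_network()] or [weighted_network()].
#' @return nonnegative real spectral radius.
#' @export
dominant_eigenvalue <- function(net) {
  M <- as_influence_matrix(net)
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}
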