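#' Directed interaction networks
#'
#' A `directed_network` holds the binary influence matrix `M` of a networked
#' dynamical system: `M[i, j] = 1` if and only if there is a directed link
#' from node `j` to node `i` (node `j` influences node `i`).
#' Self-interactions are excluded, so the diagonal is zero.  A
#' `weighted_network` relaxes the entries to arbitrary nonnegative reals
#' with the same orientation convention.
#'
#' @param adjacency square 0/1 matrix with zero diagonal, oriented as above.
#' @return An object of class `directed_network`: the adjacency matrix
#'   (integer storage) with the class attribute set.
#' @examples
#' ring <- cycle_network(4)
#' n_nodes(ring)
#' @export
directed_network <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0))
    stop("self-interactions are excluded: diagonal must be zero")
  storage.mode(adjacency) <- "integer"
  structure(adjacency, class = c("directed_network", "matrix", "array"))
}

#' @rdname directed_network
#' @param weights square nonnegative matrix with zero diagonal.
#' @export
weighted_network <- function(weights) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("weights must be square")
  if (any(weights < 0))
    stop("weights must be nonnegative")
  if (any(diag(weights) != 0))
    stop("self-interactions are excluded: diagonal must be zero")
  storage.mode(weights) <- "double"
  structure(weights, class = c("weighted_network", "matrix", "array"))
}

#' @rdname directed_network
#' @param net a `directed_network` or `weighted_network`.
#' @export
n_nodes <- function(net) nrow(net)

#' @rdname directed_network
#' @export
adjacency <- function(net) {
  m <- unclass(net)
  attr(m, "class") <- NULL
  m
}

# plain influence matrix from either network flavour or a bare matrix
as_influence_matrix <- function(net) {
  m <- as.matrix(unclass(net))
  storage.mode(m) <- "double"
  m
}

is_binary_network <- function(net) {
  all(unclass(net) %in% c(0, 1))
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed network: %d nodes, %d links\n",
              nrow(x), sum(unclass(x))))
  invisible(x)
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted network: %d nodes, %d links\n",
              nrow(x), sum(unclass(x) > 0)))
  invisible(x)
}

#' A single directed N-cycle
#'
#' Convenience constructor for the isolated cycle `1 -> 2 -> ... -> n -> 1`,
#' optionally embedded in a larger node set (extra nodes isolated).
#'
#' @param n cycle length (>= 2).
#' @param n_nodes total number of nodes (defaults to `n`).
#' @return a [directed_network()].
#' @export
cycle_network <- function(n, n_nodes = n) {
  stopifnot(n >= 2, n_nodes >= n)
  A <- matrix(0L, n_nodes, n_nodes)
  for (j in seq_len(n)) A[j %% n + 1L, j] <- 1L
  directed_network(A)
}

#' Sample a directed Erdős–Rényi network
#'
#' Each ordered pair `(j, i)` with `i != j` carries a directed link `j -> i`
#' independently with probability `c / (n_nodes - 1)`, so `c` is the mean
#' in-degree (and out-degree).  Uses R's global RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param c mean degree, `0 <= c <= n_nodes - 1`.
#' @return a [directed_network()].
#' @examples
#' set.seed(1)
#' net <- sample_er(50, c = 1)
#' @export
sample_er <- function(n_nodes, c) {
  if (c < 0 || c > n_nodes - 1)
    stop("mean degree c must lie in [0, n_nodes - 1]")
  p <- c / (n_nodes - 1)
  A <- matrix(as.integer(runif(n_nodes * n_nodes) < p), n_nodes, n_nodes)
  diag(A) <- 0L
  directed_network(A)
}
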