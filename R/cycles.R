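#' Enumerate simple directed cycles
#'
#' Lists every simple directed cycle (a directed closed path whose only
#' repeated vertex is the first/last) of a directed network, each cycle
#' reported once, canonicalized to start at its smallest node index.
#' Enumeration is depth-first from each anchor node over nodes with larger
#' indices, so each cycle is found exactly at its minimal node; it can be
#' stopped early after `max_count` cycles, which bounds the cost on dense
#' graphs when only a predicate such as "at least two cycles" is needed.
#'
#' @param net a [directed_network()].
#' @param max_count stop after this many cycles (default `Inf`).
#' @return A `cycle_census` list: `cycle_count`, `cycles` (list of integer
#'   node sequences, 1-based), and `capped` (`TRUE` iff enumeration stopped
#'   at `max_count`).
#' @examples
#' count_cycles(cycle_network(5))$cycle_count  # 1
#' @export
count_cycles <- function(net, max_count = Inf) {
  A <- unclass(as.matrix(net))
  n <- nrow(A)
  succ <- lapply(seq_len(n), function(j) which(A[, j] != 0))
  cycles <- list()
  capped <- FALSE

  for (s in seq_len(n)) {
    if (capped) break
    # DFS over nodes >= s; a return edge to s closes a cycle anchored at s
    path <- integer(0)
    onpath <- logical(n)
    visit <- function(u) {
      if (capped) return(invisible(NULL))
      path[[length(path) + 1L]] <<- u
      onpath[u] <<- TRUE
      for (v in succ[[u]]) {
        if (capped) break
        if (v == s) {
          cycles[[length(cycles) + 1L]] <<- path
          if (length(cycles) >= max_count) capped <<- TRUE
        } else if (v > s && !onpath[v]) {
          visit(v)
        }
      }
      onpath[u] <<- FALSE
      path <<- path[-length(path)]
      invisible(NULL)
    }
    visit(s)
  }
  structure(list(cycle_count = length(cycles), cycles = cycles,
                 capped = capped),
            class = "cycle_census")
}

#' @export
print.cycle_census <- function(x, ...) {
  cat(sprintf("cycle census: %s%d simple directed cycle(s)\n",
              if (x$capped) ">= " else "", x$cycle_count))
  invisible(x)
}

#' Fast exact cycle predicates
#'
#' Computes "contains at least one cycle" and "contains exactly one cycle"
#' via strongly connected components: every simple directed cycle lies in a
#' nontrivial SCC, and a nontrivial SCC holds exactly one cycle iff its
#' internal link count equals its node count.  Equivalent to the predicates
#' derivable from [count_cycles()] with `max_count = 2`, at linear cost.
#'
#' @param net a [directed_network()].
#' @return list with `has_cycle`, `single_cycle`, `n_cyclic_scc`, and
#'   `cycle_nodes` (members of the unique cycle when `single_cycle`).
#' @export
cycle_flags <- function(net) {
  A <- unclass(as.matrix(net))
  storage.mode(A) <- "integer"
  cpp_cycle_flags(A)
}

#' Cycle-to-node path multiplicity
#'
#' For a network containing exactly one simple directed cycle, returns for
#' every node the number `n_i` of distinct directed paths leading from
#' cycle-nodes to node `i`: `n_i = 1` on the cycle itself, `n_i = 0` for
#' nodes unreachable from the cycle, and otherwise the sum of `n_j` over
#' in-neighbours `j`, evaluated in topological order of the off-cycle part
#' (acyclic by assumption).  These integers are the structural ground truth
#' that the state-vector quantization levels must reproduce.
#'
#' @param net a [directed_network()] with exactly one simple cycle.
#' @return integer vector of path counts, one per node.
#' @examples
#' A <- matrix(0, 4, 4)
#' A[2, 1] <- A[3, 2] <- A[1, 3] <- 1  # 3-cycle
#' A[4, 1] <- A[4, 2] <- 1             # two paths into node 4
#' path_multiplicity(directed_network(A))  # 1 1 1 2
#' @export
path_multiplicity <- function(net) {
  flags <- cycle_flags(net)
  if (!flags$single_cycle)
    stop("path_multiplicity requires a network with exactly one simple cycle")
  A <- unclass(as.matrix(net))
  n <- nrow(A)
  on_cycle <- logical(n)
  on_cycle[flags$cycle_nodes] <- TRUE

  counts <- integer(n)
  counts[on_cycle] <- 1L

  # Kahn topological order of the off-cycle subgraph (cycle nodes removed);
  # in-links from cycle nodes contribute their fixed count of 1.
  off <- which(!on_cycle)
  if (length(off)) {
    sub <- A[off, off, drop = FALSE]
    indeg <- rowSums(sub)
    queue <- off[indeg == 0]
    remaining <- indeg
    names(remaining) <- off
    order_off <- integer(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      order_off <- c(order_off, u)
      out_to <- off[sub[, match(u, off)] != 0]
      for (v in out_to) {
        key <- as.character(v)
        remaining[key] <- remaining[key] - 1L
        if (remaining[key] == 0) queue <- c(queue, v)
      }
    }
    for (u in order_off)
      counts[u] <- sum(A[u, ] * counts)
  }
  counts
}

#' Rejection-sample a conditioned Erdős–Rényi network
#'
#' Draws from [sample_er()] until the cycle structure matches `condition`:
#' `"single_cycle"` keeps draws with exactly one simple directed cycle
#' (optionally requiring some node to be reachable from the cycle by at
#' least `min_max_multiplicity` distinct paths), `"multi_cycle"` keeps draws
#' with at least two cycles.
#'
#' @inheritParams sample_er
#' @param condition `"single_cycle"` or `"multi_cycle"`.
#' @param min_max_multiplicity for `"single_cycle"`: required maximum of
#'   [path_multiplicity()] over nodes (0 disables the extra condition).
#' @param max_attempts rejection budget before giving up.
#' @return a [directed_network()] with attribute `"attempts"`.
#' @export
sample_conditioned <- function(n_nodes, c,
                               condition = c("single_cycle", "multi_cycle"),
                               min_max_multiplicity = 0,
                               max_attempts = 1e5) {
  condition <- match.arg(condition)
  stopifnot(max_attempts >= 1)
  for (attempt in seq_len(max_attempts)) {
    net <- sample_er(n_nodes, c)
    flags <- cycle_flags(net)
    ok <- if (condition == "single_cycle") flags$single_cycle
          else flags$has_cycle && !flags$single_cycle
    if (ok && condition == "single_cycle" && min_max_multiplicity > 0)
      ok <- max(path_multiplicity(net)) >= min_max_multiplicity
    if (ok) {
      attr(net, "attempts") <- attempt
      return(net)
    }
  }
  stop(sprintf("sample_conditioned: no %s draw in %d attempts",
               condition, max_attempts))
}
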