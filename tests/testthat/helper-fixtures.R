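# small structured networks used across tests

# 3-cycle 1->2->3->1 with two extra links 1->4 and 2->4: the canonical
# quantization fixture (attractor 0.2, 0.2, 0.2, 0.4; path counts 1 1 1 2)
fixture_cycle_fan <- function() {
  A <- matrix(0, 4, 4)
  A[2, 1] <- A[3, 2] <- A[1, 3] <- 1
  A[4, 1] <- A[4, 2] <- 1
  directed_network(A)
}

# acyclic chain 1 -> 2 -> ... -> n
fixture_chain <- function(n) {
  A <- matrix(0, n, n)
  for (j in seq_len(n - 1)) A[j + 1, j] <- 1
  directed_network(A)
}

# brute-force simple-cycle enumeration for tiny networks: checks every
# subset and cyclic order directly against the adjacency matrix
brute_force_cycles <- function(net) {
  A <- unclass(as.matrix(net))
  n <- nrow(A)
  found <- list()
  for (size in 2:n) {
    subsets <- combn(n, size, simplify = FALSE)
    for (sub in subsets) {
      rest <- sub[-1]
      perms <- if (length(rest) == 1) list(rest) else all_perms(rest)
      for (p in perms) {
        cyc <- c(sub[1], p)
        ok <- TRUE
        for (k in seq_along(cyc)) {
          from <- cyc[k]
          to <- cyc[k %% length(cyc) + 1]
          if (A[to, from] == 0) { ok <- FALSE; break }
        }
        if (ok) found[[length(found) + 1]] <- cyc
      }
    }
  }
  found
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# canonical form of a cycle list for set comparison
canon_cycles <- function(cycles) {
  sort(vapply(cycles, function(cyc) paste(cyc, collapse = "-"), character(1)))
}
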