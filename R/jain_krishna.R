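#' Jain-Krishna co-evolutionary ecosystem model
#'
#' A two-timescale toy ecosystem: on the fast timescale species abundances
#' relax to the normalized attractor of the linear catalytic dynamics on a
#' fixed interaction network; on the slow timescale the species with the
#' smallest relative abundance is eliminated (with all its links) and
#' replaced by a newcomer that links to each existing species independently
#' with probability `m / (N - 1)`, in both directions.  For `m < 1` the
#' model shows punctuated growth and recurrent collapses: every collapse is
#' preceded by a phase where exactly one cycle remains -- the phase the
#' quantization signal detects.
#'
#' `jk_init()` draws the initial Erdős–Rényi network with link probability
#' `m / (N - 1)`; `jk_step()` performs one slow-timescale update.
#'
#' @param n_nodes number of species `N` (conserved by the dynamics).
#' @param m mean connectivity of a newcomer (collapse regime: `0 < m < 1`).
#' @return `jk_init()`: a [directed_network()].  `jk_step()`: list with the
#'   updated `net`, the replaced `weakest` node index, and the `attractor`
#'   result (computed on the pre-update network) that selected it.
#' @examples
#' set.seed(7)
#' net <- jk_init(25, m = 0.25)
#' step <- jk_step(net, m = 0.25)
#' @export
jk_init <- function(n_nodes, m) {
  stopifnot(m >= 0, m <= n_nodes - 1)
  sample_er(n_nodes, m)
}

#' @rdname jk_init
#' @param net current interaction network.
#' @export
jk_step <- function(net, m) {
  att <- attractor(net)
  st <- jk_structure(net)
  net2 <- jk_replace(net, m, st$weak)
  list(net = net2$net, weakest = net2$weakest, attractor = att)
}

# Attractor structure of one network, resolved exactly from topology where
# possible (acyclic: longest-chain ends; single cycle: integer path
# multiplicity), else by power iteration: S (support size), structural
# cycle flags, and the weakest-candidate set (zeros if any, else the
# minimal positive attractor level).
jk_structure <- function(net) {
  A <- unclass(as.matrix(net))
  storage.mode(A) <- "integer"
  cpp_jk_structure(A)
}

# eliminate one node from the weakest set (ties broken uniformly at random)
# and wire in a newcomer at the same index
jk_replace <- function(net, m, weak_set) {
  A <- unclass(as.matrix(net))
  n <- nrow(A)
  w <- if (length(weak_set) == 1) weak_set
       else weak_set[floor(runif(1) * length(weak_set)) + 1]
  A[w, ] <- 0L
  A[, w] <- 0L
  p <- m / (n - 1)
  others <- setdiff(seq_len(n), w)
  A[w, others] <- as.integer(runif(n - 1) < p)  # in-links j -> w
  A[others, w] <- as.integer(runif(n - 1) < p)  # out-links w -> j
  list(net = directed_network(A), weakest = w)
}

#' Run the Jain-Krishna model and record per-step diagnostics
#'
#' At every slow-timescale step, records the diversity
#' `S = #\{i : x_i > 0\}` (support of the attractor above the zero
#' threshold), the non-structural quantization flag of the attractor, the
#' census-verified structural flags `has_cycle` / `single_cycle`, and
#' optionally the dominant eigenvalue `lambda1` -- all evaluated on the
#' network *before* that step's replacement.  Structural flags come from
#' exact strongly-connected-component predicates, so the signal can be
#' scored against ground truth instead of being assumed.
#'
#' @inheritParams jk_init
#' @param n_steps number of slow-timescale updates.
#' @param seed optional integer seed making the run self-reproducible.
#' @param record_lambda1 also record the spectral radius each step
#'   (an extra dense eigensolve; disable for long harvest runs).
#' @param record_states keep the attractor vector of every step (rows of
#'   `$states`), e.g. for the baseline time-series precursors.
#' @param init optional starting network (default: [jk_init()]).
#' @return list of class `jk_run`: `records` data frame (`step`, `S`,
#'   `lambda1`, `quantized`, `has_cycle`, `single_cycle`), `states`
#'   (matrix or `NULL`), and `params`.
#' @examples
#' run <- jk_run(25, m = 0.25, n_steps = 50, seed = 1)
#' head(run$records)
#' @export
jk_run <- function(n_nodes, m, n_steps, seed = NULL,
                   record_lambda1 = TRUE, record_states = FALSE,
                   init = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  net <- if (is.null(init)) jk_init(n_nodes, m) else init
  S <- integer(n_steps)
  lambda1 <- rep(NA_real_, n_steps)
  quantized <- has_cycle <- single_cycle <- logical(n_steps)
  states <- if (record_states) matrix(NA_real_, n_steps, n_nodes) else NULL

  for (t in seq_len(n_steps)) {
    st <- jk_structure(net)
    x <- attractor(net)$x
    S[t] <- st$S
    quantized[t] <- detect_quantization(x)$is_quantized
    has_cycle[t] <- st$has_cycle
    single_cycle[t] <- st$single_cycle
    if (record_lambda1) lambda1[t] <- dominant_eigenvalue(net)
    if (record_states) states[t, ] <- x
    net <- jk_replace(net, m, st$weak)$net
  }
  structure(list(
    records = data.frame(step = seq_len(n_steps), S = S, lambda1 = lambda1,
                         quantized = quantized, has_cycle = has_cycle,
                         single_cycle = single_cycle),
    states = states,
    params = list(n_nodes = n_nodes, m = m, n_steps = n_steps, seed = seed)),
    class = "jk_run")
}

#' @export
print.jk_run <- function(x, ...) {
  cr <- collapse_records(x)
  cat(sprintf("Jain-Krishna run: N = %d, m = %g, %d steps, %d collapse(s)\n",
              x$params$n_nodes, x$params$m, x$params$n_steps,
              cr$stats$n_collapses))
  invisible(x)
}

#' Scalable Jain-Krishna run for collapse statistics
#'
#' Runs the slow-timescale loop entirely in compiled code, recording per
#' step the structural flags and the diversity `S`, and optionally stopping
#' as soon as a target number of collapses has been observed.  The weakest
#' node is resolved exactly from the topology where the attractor structure
#' is determined by it (acyclic and single-cycle networks) and by power
#' iteration otherwise; the RNG draws match [jk_run()] exactly, so under
#' the same seed both produce the same trajectory.  Use this for long
#' harvest runs; [jk_run()] additionally records the non-structural
#' quantization diagnostics.
#'
#' @inheritParams jk_run
#' @param n_steps maximal number of steps.
#' @param stop_after_collapses stop early once this many collapses have
#'   been recorded (0 = never).
#' @return a `jk_run` object (the `lambda1` and `quantized` columns are
#'   `NA`: this runner records structure only).
#' @export
jk_harvest <- function(n_nodes, m, n_steps, stop_after_collapses = 0,
                       seed = NULL, init = NULL) {
  stopifnot(n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  net <- if (is.null(init)) jk_init(n_nodes, m) else init
  A <- unclass(as.matrix(net))
  storage.mode(A) <- "integer"
  res <- cpp_jk_run(A, m, as.integer(n_steps),
                    as.integer(stop_after_collapses))
  k <- res$steps_run
  structure(list(
    records = data.frame(step = seq_len(k), S = res$S,
                         lambda1 = NA_real_, quantized = NA,
                         has_cycle = res$has_cycle,
                         single_cycle = res$single_cycle),
    states = NULL,
    params = list(n_nodes = n_nodes, m = m, n_steps = n_steps, seed = seed)),
    class = "jk_run")
}

#' Locate collapses and score the time-to-collapse prediction
#'
#' A collapse is the structural transition from a cycle-bearing network to
#' a cycle-free one (`has_cycle` TRUE -> FALSE).  For each collapse the
#' record holds `t_collapse` (first cycle-free step), `t_cycl` (first step
#' of the maximal contiguous single-cycle phase immediately preceding it)
#' and the lead time `T = t_collapse - t_cycl`.  A collapse not preceded by
#' a single-cycle step would contradict the collapse mechanism and raises a
#' consistency error.  The summary compares the sample mean of `T` with the
#' analytic expectation `e/m`.
#'
#' @param run a [jk_run()] result, or a data frame with logical columns
#'   `has_cycle` and `single_cycle`.
#' @param m connectivity used for the `e/m` comparison (taken from the run
#'   parameters when available).
#' @return list: `records` data frame (`t_cycl`, `t_collapse`, `T`) and
#'   `stats` (`n_collapses`, `mean_T`, `expected_T = e/m`, `ratio`).
#' @export
collapse_records <- function(run, m = NULL) {
  if (inherits(run, "jk_run")) {
    if (is.null(m)) m <- run$params$m
    rec <- run$records
  } else rec <- as.data.frame(run)
  stopifnot(all(c("has_cycle", "single_cycle") %in% names(rec)))
  h <- rec$has_cycle
  s <- rec$single_cycle
  if (any(s & !h)) stop("inconsistent run data: single_cycle without has_cycle")
  n <- length(h)
  t_collapse <- which(!h & c(FALSE, head(h, -1L)))
  t_cycl <- integer(length(t_collapse))
  for (k in seq_along(t_collapse)) {
    t <- t_collapse[k]
    if (!s[t - 1L])
      stop("inconsistent run data: collapse not preceded by a single-cycle step")
    u <- t - 1L
    while (u > 1L && s[u - 1L]) u <- u - 1L
    t_cycl[k] <- u
  }
  Tlead <- t_collapse - t_cycl
  stats <- list(n_collapses = length(Tlead),
                mean_T = if (length(Tlead)) mean(Tlead) else NA_real_,
                expected_T = if (is.null(m)) NA_real_ else exp(1) / m,
                m = if (is.null(m)) NA_real_ else m)
  stats$ratio <- stats$mean_T / stats$expected_T
  list(records = data.frame(t_cycl = t_cycl, t_collapse = t_collapse,
                            T = Tlead),
       stats = stats)
}

#' Analytic time-to-collapse in the single-cycle phase
#'
#' Once a single cycle remains, each slow-timescale update removes a
#' cycle-node with probability `p = p_w * p_c`: `p_w ~ m` is the chance the
#' cycle-node is among the weakest (a newcomer survives only if it receives
#' an in-link, probability `~ m`), and `p_c ~ 1/e` the chance of picking it
#' from that set.  The lead time is then geometric,
#' `P(T) = (1 - p)^(T-1) p`, with mean `<T> = 1/p = e/m`.
#'
#' @param m mean connectivity (`> 0`).
#' @return list of class `collapse_theory`: `m`, `p_w`, `p_c`, `p`,
#'   `expected_T`, and `pmf(T)` (the geometric probability mass function).
#' @examples
#' predicted_time_to_collapse(0.25)$expected_T  # e / 0.25
#' @export
predicted_time_to_collapse <- function(m) {
  if (m <= 0) stop("m must be positive")
  p <- m / exp(1)
  structure(list(m = m, p_w = m, p_c = 1 / exp(1), p = p,
                 expected_T = 1 / p,
                 pmf = function(T) (1 - p)^(T - 1) * p),
            class = "collapse_theory")
}

#' @export
print.collapse_theory <- function(x, ...) {
  cat(sprintf("collapse theory: m = %g, p = m/e = %.4g, <T> = e/m = %.4g\n",
              x$m, x$p, x$expected_T))
  invisible(x)
}
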