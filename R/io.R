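#' Read and write directed networks as edge-list TSV
#'
#' The on-disk format is a two-column tab-separated file with header
#' `source<TAB>target` and 0-based node ids: one row `(j, i)` per directed
#' link `j -> i`, which the reader maps to `adjacency[i, j] = 1` (the
#' package-wide "link from j to i" orientation).  Writing then reading a
#' network is the identity.
#'
#' @param path file path.
#' @param n_nodes declared node count; default is `max(id) + 1` from the
#'   file (must be given for edgeless files or when isolated high-index
#'   nodes exist).
#' @return `read_edge_list()`: a [directed_network()].
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "integer", comment.char = "#")
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list must have columns 'source' and 'target'")
  if (nrow(df) && any(df$source == df$target))
    stop("self-loop row found: self-interactions are excluded (M_ii = 0)")
  if (anyDuplicated(df)) {
    warning("duplicate edge rows collapsed")
    df <- unique(df)
  }
  if (is.null(n_nodes))
    n_nodes <- if (nrow(df)) max(df$source, df$target) + 1L else
      stop("n_nodes must be given for an edgeless file")
  if (nrow(df) && max(df$source, df$target) >= n_nodes)
    stop("node id exceeds declared n_nodes")
  A <- matrix(0L, n_nodes, n_nodes)
  if (nrow(df)) A[cbind(df$target + 1L, df$source + 1L)] <- 1L
  directed_network(A)
}

#' @rdname read_edge_list
#' @param net a [directed_network()].
#' @export
write_edge_list <- function(net, path) {
  A <- unclass(as.matrix(net))
  idx <- which(A != 0, arr.ind = TRUE)
  df <- data.frame(source = idx[, "col"] - 1L, target = idx[, "row"] - 1L)
  df <- df[order(df$source, df$target), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# directed edge list: one row per link source -> target (0-based ids)",
             con)
  writeLines("source\ttarget", con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the igraph package")
  A <- unclass(as.matrix(net))
  g <- igraph::graph_from_adjacency_matrix(t(A), mode = "directed")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Machine-readable run report
#'
#' Serializes analysis results together with the full parameter set and
#' seed into a schema-versioned JSON document, so that every stochastic run
#' can be reproduced and compared.
#'
#' @param results named list of payloads (coerced by jsonlite; the package's
#'   report classes are plain lists and serialize directly).
#' @param params named list of parameters, ideally including `seed`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
run_report <- function(results, params = list(), path = NULL) {
  doc <- list(schema = "cyclewarn-report/1",
              params = params,
              results = rapply(results, unclass, how = "replace"))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
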