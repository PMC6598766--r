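#' Similarity network from a similarity matrix
#'
#' Thresholds the pairwise similarity matrix into an undirected graph:
#' compounds with similarity strictly greater than `threshold` are joined
#' by an edge weighted by that similarity. A pair at exactly the threshold
#' is not connected. Node attributes (category, counter-screen class,
#' library) can be attached for export.
#'
#' @param m Similarity matrix from [similarity_matrix()].
#' @param threshold Edge threshold in `[0, 1]`; default 0.5.
#' @param node_attrs Optional data.frame with a `compound_id` column and any
#'   further columns to attach as node attributes.
#' @return An object of class `"zf_network"`: list with `graph` (igraph),
#'   `threshold`.
#' @export
build_network <- function(m, threshold = 0.5, node_attrs = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("cmp", seq_len(nrow(m)))
  adj <- (m > threshold) * m
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(node_attrs)) {
    stopifnot("compound_id" %in% names(node_attrs))
    idx <- match(ids, node_attrs$compound_id)
    for (col in setdiff(names(node_attrs), "compound_id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
    }
  }
  structure(list(graph = g, threshold = threshold), class = "zf_network")
}

#' @export
print.zf_network <- function(x, ...) {
  cat(sprintf("<similarity network: %d nodes, %d edges, threshold %g>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Extract structural clusters from a similarity network
#'
#' Connected components with at least `min_size` members, largest first.
#' Screens of this design follow up components of five or more compounds as
#' candidate structure-activity families.
#'
#' @param net A `"zf_network"` from [build_network()].
#' @param min_size Minimum component size to report.
#' @return A list of character vectors of compound ids, sorted by decreasing
#'   size (ties broken by first member id).
#' @export
extract_clusters <- function(net, min_size = 5L) {
  stopifnot(inherits(net, "zf_network"))
  comp <- igraph::components(net$graph)
  groups <- split(igraph::V(net$graph)$name, comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) == 0L) return(list())
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1L))
  unname(groups[ord])
}

#' Export a similarity network
#'
#' Writes GraphML (attributes preserved) or SIF (Cytoscape simple
#' interaction format, one `id_a sim id_b` line per edge).
#'
#' @param net A `"zf_network"`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @export
export_network <- function(net, path, format = c("graphml", "sif")) {
  stopifnot(inherits(net, "zf_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net$graph)
    lines <- if (nrow(el) > 0) paste(el[, 1], "sim", el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(net$graph)$name, as.vector(el))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Read a GraphML network back
#'
#' @param path GraphML file written by [export_network()].
#' @param threshold Threshold to record on the restored object.
#' @return A `"zf_network"`.
#' @export
import_network <- function(path, threshold = 0.5) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g, threshold = threshold), class = "zf_network")
}

#' Order triage records for a heatmap display
#'
#' Sorts compounds by decreasing counter-screen (mbp) average so the
#' strongest rescue sits at the top; ties break lexicographically by
#' compound id so the order is deterministic. Records with a missing mbp
#' average are placed last and flagged.
#'
#' @param records A data.frame with columns `compound_id` and `mbp_average`.
#' @return The records reordered, with a logical `mbp_missing` column added.
#' @export
order_heatmap <- function(records) {
  stopifnot(all(c("compound_id", "mbp_average") %in% names(records)))
  records$mbp_missing <- is.na(records$mbp_average)
  key <- records$mbp_average
  key[records$mbp_missing] <- -Inf
  ord <- order(-key, records$compound_id)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
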