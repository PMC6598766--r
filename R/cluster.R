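#' Ward clustering of a similarity matrix
#'
#' Agglomerative hierarchical clustering on the distance transform
#' `d = 1 - similarity`, using Ward's minimum-variance criterion
#' (`stats::hclust`, method `"ward.D2"`). The leaf order is the plain
#' left-to-right dendrogram traversal, with no optimal-leaf-ordering
#' post-pass.
#'
#' @param m Similarity matrix from [similarity_matrix()] (or any symmetric
#'   matrix with unit diagonal and values in `[0, 1]`).
#' @return An object of class `"zf_dendro"`: a list with `linkage` (a
#'   data.frame of merge records: `left`, `right`, `height`, `size`, using
#'   `hclust` merge conventions), `leaf_order` (1-based permutation),
#'   `labels`, and the underlying `hclust` object.
#' @export
ward_cluster <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  if (n == 0L) stop("empty similarity matrix")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("cmp", seq_len(n))
  if (n == 1L) {
    return(structure(list(
      linkage = data.frame(left = integer(0), right = integer(0),
                           height = numeric(0), size = integer(0)),
      leaf_order = 1L, labels = labels, hclust = NULL
    ), class = "zf_dendro"))
  }
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = "ward.D2")
  sizes <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    l <- hc$merge[k, 1]; r <- hc$merge[k, 2]
    sizes[k] <- (if (l < 0) 1L else sizes[l]) + (if (r < 0) 1L else sizes[r])
  }
  structure(list(
    linkage = data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height, size = sizes),
    leaf_order = hc$order,
    labels = labels,
    hclust = hc
  ), class = "zf_dendro")
}

#' @export
print.zf_dendro <- function(x, ...) {
  cat(sprintf("<Ward dendrogram: %d leaves, %d merges>\n",
              length(x$leaf_order), nrow(x$linkage)))
  invisible(x)
}

#' Write the linkage merge table as CSV
#'
#' @param x A `"zf_dendro"` object.
#' @param path Output CSV path.
#' @export
write_linkage <- function(x, path) {
  stopifnot(inherits(x, "zf_dendro"))
  utils::write.csv(x$linkage, path, row.names = FALSE)
  invisible(path)
}
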