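#' Polar scatterplot coordinates for a screened library
#'
#' Places each compound on a polar plot: the angle encodes its position on
#' the structural similarity dendrogram (structurally related compounds sit
#' on nearby radii) and the radius encodes its primary-screen category, on
#' equally spaced concentric rings with A innermost and G outermost. Seeded
#' uniform jitter, bounded so the angular order is preserved, separates
#' overplotted points; the seed is recorded in the output so layouts are
#' reproducible.
#'
#' @param order A `"zf_dendro"` from [ward_cluster()].
#' @param categories Character vector of categories `A`-`G`, aligned with
#'   the rows of the clustered matrix.
#' @param jitter_seed Integer seed for the jitter stream.
#' @param jitter Logical; `FALSE` gives the exact grid positions.
#' @param ring_radii Named numeric vector mapping categories to ring radii.
#' @return A data.frame of class `"zf_polar"` with columns `compound_id`,
#'   `angle` (radians in `[0, 2*pi)`), `radius`, `category`, plus attributes
#'   `jitter_seed` and `ring_radii`.
#' @export
polar_layout <- function(order, categories, jitter_seed = 1L, jitter = TRUE,
                         ring_radii = stats::setNames(1:7, LETTERS[1:7])) {
  stopifnot(inherits(order, "zf_dendro"))
  n <- length(order$leaf_order)
  categories <- as.character(categories)
  if (length(categories) != n) {
    stop("categories must align with the clustered compounds")
  }
  unknown <- setdiff(unique(categories), names(ring_radii))
  if (length(unknown) > 0) {
    stop("unknown categories: ", paste(unknown, collapse = ", "))
  }
  # rank of each compound along the dendrogram circumference (0-based)
  rank0 <- match(seq_len(n), order$leaf_order) - 1L
  spacing <- 2 * pi / n
  band <- 0.35  # radial half-width of a category ring
  jit <- if (jitter && n > 1) {
    with_seed(jitter_seed, list(
      ang = stats::runif(n, -0.45, 0.45) * spacing,
      rad = stats::runif(n, -band, band)
    ))
  } else {
    list(ang = numeric(n), rad = numeric(n))
  }
  # jitter is bounded below half the spacing, so only the first leaf can dip
  # under 0; clamping it preserves both the [0, 2*pi) range and strict
  # angular order along the dendrogram
  out <- data.frame(
    compound_id = order$labels,
    angle = pmax(rank0 * spacing + jit$ang, 0),
    radius = unname(ring_radii[categories]) + jit$rad,
    category = categories,
    stringsAsFactors = FALSE
  )
  attr(out, "jitter_seed") <- jitter_seed
  attr(out, "ring_radii") <- ring_radii
  class(out) <- c("zf_polar", "data.frame")
  out
}

#' Plot a polar layout
#'
#' Base-graphics rendering of [polar_layout()] coordinates: one point per
#' compound on its category ring.
#'
#' @param x A `"zf_polar"` data.frame.
#' @param col Optional vector of colours per category (named).
#' @param ... Passed to [graphics::points()].
#' @export
plot.zf_polar <- function(x, col = NULL, ...) {
  r <- max(x$radius) + 0.5
  graphics::plot(NA, xlim = c(-r, r), ylim = c(-r, r), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Library polar layout")
  rings <- attr(x, "ring_radii")
  th <- seq(0, 2 * pi, length.out = 200)
  for (rr in rings) graphics::lines(rr * cos(th), rr * sin(th), col = "grey85")
  if (is.null(col)) {
    col <- stats::setNames(grDevices::hcl.colors(length(rings), "Zissou 1"),
                           names(rings))
  }
  graphics::points(x$radius * cos(x$angle), x$radius * sin(x$angle),
                   col = col[x$category], pch = 16, cex = 0.5, ...)
  invisible(x)
}

#' Write polar layout coordinates as CSV
#'
#' @param x A `"zf_polar"` data.frame.
#' @param path Output CSV path. The jitter seed is written as a comment-free
#'   `jitter_seed` column so the file is self-describing.
#' @export
write_polar_layout <- function(x, path) {
  stopifnot(inherits(x, "zf_polar"))
  df <- as.data.frame(x)
  df$jitter_seed <- attr(x, "jitter_seed")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
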