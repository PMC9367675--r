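# Thin, optional rendering layer over the exported numeric matrices.
# The heatmap semantics carry no tested guarantees; the numeric tables
# written by write_results() are the authoritative output.

#' Heatmap of a pairwise distance matrix
#'
#' Renders the cell-by-cell distance matrix (rows and columns ordered by
#' cell id) with pheatmap when available.  Blue = far, red = close,
#' mirroring the usual display convention for proximity heatmaps.
#'
#' @param x a `distance_pair_matrix` from [pairwise_distances()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_distance_heatmap <- function(x, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_distance_heatmap needs the 'pheatmap' package", call. = FALSE)
  m <- x$values
  rownames(m) <- x$row_ids
  colnames(m) <- x$col_ids
  ord_r <- order(x$row_ids, method = "radix")
  ord_c <- order(x$col_ids, method = "radix")
  p <- pheatmap::pheatmap(m[ord_r, ord_c, drop = FALSE],
                          cluster_rows = FALSE, cluster_cols = FALSE,
                          color = grDevices::colorRampPalette(
                            c("red", "white", "blue"))(100), ...)
  invisible(p)
}

#' Heatmap of neighborhood counts
#'
#' One row per center cell, one column per circle size; color encodes
#' the neighbor count (red = more, blue = fewer).
#'
#' @param ... one or more `neighborhood_counts` objects over the same
#'   centers (e.g. at 15 and 25 um).
#' @param pheatmap_args list of extra arguments for pheatmap.
#' @return the pheatmap object, invisibly.
#' @export
plot_count_heatmap <- function(..., pheatmap_args = list()) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_count_heatmap needs the 'pheatmap' package", call. = FALSE)
  ncs <- list(...)
  stopifnot(length(ncs) > 0)
  ids <- ncs[[1]]$center_ids
  m <- vapply(ncs, function(nc) {
    stopifnot(identical(nc$center_ids, ids))
    as.numeric(nc$counts)
  }, numeric(length(ids)))
  rownames(m) <- ids
  colnames(m) <- vapply(ncs, function(nc)
    sprintf("%s_%g", nc$neighbor_type %||% "count", nc$circle_size), "")
  ord <- order(ids, method = "radix")
  p <- do.call(pheatmap::pheatmap,
               c(list(m[ord, , drop = FALSE], cluster_rows = FALSE,
                      cluster_cols = FALSE,
                      color = grDevices::colorRampPalette(
                        c("blue", "white", "red"))(100)),
                 pheatmap_args))
  invisible(p)
}
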