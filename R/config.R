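#' Analysis configuration
#'
#' Bundles the settings of the spatial analysis: the phenotype panel, the
#' circle sizes of the neighborhood counts (15 and 25 microns by default,
#' interpreted as diameters), how the median cross-type distance is
#' formed, the circle boundary rule, and how ROI-level results pool into
#' sample-level summaries.
#'
#' @param panel a [phenotype_panel()]; defaults to [default_panel()].
#' @param type_a,type_b the two phenotype labels whose proximity is
#'   analysed (`"ILC2"` and `"Treg"` by default).
#' @param circle_sizes strictly positive, strictly increasing circle
#'   sizes in microns.
#' @param size_is_diameter logical; when `TRUE` (default) the circle size
#'   is a diameter and the radius is `size / 2`.
#' @param median_mode `"pooled"` (median over the concatenated directed
#'   nearest-neighbor vectors; default) or `"per_direction"`.
#' @param boundary `"inclusive"` (`distance <= r`, default) or
#'   `"exclusive"` (`< r`).
#' @param pooling `"per_sample"` (pool ROI-level distance vectors before
#'   taking sample medians; default) or `"per_roi"`.
#' @param topology `"plane"` (default; no edge correction) or `"torus"`
#'   (periodic distances, requires a window; used for calibration against
#'   closed-form Poisson results).
#' @param seed optional integer seed recorded for downstream
#'   randomisation (null models).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(panel = default_panel(),
                            type_a = "ILC2", type_b = "Treg",
                            circle_sizes = c(15, 25),
                            size_is_diameter = TRUE,
                            median_mode = c("pooled", "per_direction"),
                            boundary = c("inclusive", "exclusive"),
                            pooling = c("per_sample", "per_roi"),
                            topology = c("plane", "torus"),
                            seed = NULL) {
  median_mode <- match.arg(median_mode)
  boundary <- match.arg(boundary)
  pooling <- match.arg(pooling)
  topology <- match.arg(topology)
  if (length(circle_sizes) == 0 || any(circle_sizes <= 0))
    stop("circle_sizes must be strictly positive", call. = FALSE)
  if (is.unsorted(circle_sizes, strictly = TRUE))
    stop("circle_sizes must be strictly increasing", call. = FALSE)
  structure(list(panel = panel, type_a = type_a, type_b = type_b,
                 circle_sizes = circle_sizes,
                 size_is_diameter = size_is_diameter,
                 median_mode = median_mode, boundary = boundary,
                 pooling = pooling, topology = topology, seed = seed),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n",
      sprintf("  types: %s vs %s\n", x$type_a, x$type_b),
      sprintf("  circles: %s um (%s), boundary %s\n",
              paste(x$circle_sizes, collapse = ", "),
              if (x$size_is_diameter) "diameter" else "radius", x$boundary),
      sprintf("  median mode: %s; pooling: %s; topology: %s\n",
              x$median_mode, x$pooling, x$topology), sep = "")
  invisible(x)
}
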