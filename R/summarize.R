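#' Per-sample spatial summary of a classified cell table
#'
#' For every (sample, ROI) the counts of the two phenotypes of interest,
#' the median cross-type nearest-neighbor distances (pooled and per
#' direction) and, for each configured circle size, the mean and median
#' neighborhood count for all four (center, neighbor) phenotype
#' combinations.  A sample-level row (`roi_id = "(pooled)"`) follows each
#' sample's ROI rows: with `pooling = "per_sample"` (default) the
#' ROI-level distance and count vectors are concatenated before the
#' median/mean is taken; with `"per_roi"` the sample median is the median
#' of the ROI-level medians.  Distances never cross ROI boundaries: cells
#' in different tissue regions are never neighbors.
#'
#' ROIs lacking a cell of either phenotype are flagged
#' `status = "insufficient"` and excluded from the pooled medians (their
#' available neighborhood-count vectors still pool).
#'
#' @param table a classified `cell_table` (has a `phenotype` column).
#' @param config an [analysis_config()].
#' @return a tibble, one row per (sample, ROI) plus one pooled row per
#'   sample (`level` column distinguishes `"roi"` from `"sample"`).
#' @export
summarize_sample <- function(table, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!"phenotype" %in% names(table))
    stop("table has no 'phenotype' column; run classify_table() first",
         call. = FALSE)
  ta <- config$type_a; tb <- config$type_b
  sizes <- config$circle_sizes
  combos <- list(c(ta, tb), c(tb, ta), c(ta, ta), c(tb, tb))
  win <- attr(table, "window")
  win_num <- if (is.numeric(win) && length(win) == 4) win else NULL

  roi_keys <- unique(as.data.frame(table)[c("sample_id", "roi_id")])
  rows <- list()
  pools <- list()
  n_insufficient <- 0L

  for (k in seq_len(nrow(roi_keys))) {
    sid <- roi_keys$sample_id[k]; rid <- roi_keys$roi_id[k]
    sub <- table[table$sample_id == sid & table$roi_id == rid, ]
    A <- as.data.frame(sub[sub$phenotype == ta, c("cell_id", "x", "y")])
    B <- as.data.frame(sub[sub$phenotype == tb, c("cell_id", "x", "y")])
    row <- tibble::tibble(sample_id = sid, roi_id = rid, level = "roi",
                          n_a = nrow(A), n_b = nrow(B))
    prox <- median_cross_distance(A, B, mode = config$median_mode,
                                  topology = config$topology,
                                  window = win_num,
                                  type_a = ta, type_b = tb)
    row$status <- if (prox$status == "ok") "ok" else "insufficient"
    if (row$status == "insufficient") n_insufficient <- n_insufficient + 1L
    row$median_pooled <- prox$median_pooled
    row$median_a_to_b <- prox$median_a_to_b
    row$median_b_to_a <- prox$median_b_to_a

    if (is.null(pools[[sid]]))
      pools[[sid]] <- list(d_ab = numeric(0), d_ba = numeric(0),
                           roi_medians = numeric(0), counts = list())
    if (prox$status == "ok") {
      pools[[sid]]$d_ab <- c(pools[[sid]]$d_ab, prox$dists_a_to_b)
      pools[[sid]]$d_ba <- c(pools[[sid]]$d_ba, prox$dists_b_to_a)
      pools[[sid]]$roi_medians <- c(pools[[sid]]$roi_medians,
                                    prox$median_pooled)
    }

    pts <- list(); pts[[ta]] <- A; pts[[tb]] <- B
    for (size in sizes) {
      for (cmb in combos) {
        ct <- cmb[1]; nt <- cmb[2]
        nm <- sprintf("count_%s_around_%s_%g", nt, ct, size)
        if (nrow(pts[[ct]]) == 0) {
          row[[paste0("mean_", nm)]] <- NA_real_
          row[[paste0("median_", nm)]] <- NA_real_
          next
        }
        nc <- neighborhood_counts(pts[[ct]], pts[[nt]], size,
                                  size_is_diameter = config$size_is_diameter,
                                  boundary = config$boundary,
                                  topology = config$topology,
                                  window = win_num,
                                  center_type = ct, neighbor_type = nt)
        row[[paste0("mean_", nm)]] <- mean(nc$counts)
        row[[paste0("median_", nm)]] <- median(nc$counts)
        pools[[sid]]$counts[[nm]] <- c(pools[[sid]]$counts[[nm]], nc$counts)
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (n_insufficient > 0)
    message(n_insufficient,
            " ROI(s) with a missing phenotype flagged 'insufficient' and ",
            "excluded from pooled medians")

  out <- dplyr::bind_rows(rows)
  pooled_rows <- lapply(unique(roi_keys$sample_id), function(sid) {
    sub <- out[out$sample_id == sid & out$level == "roi", ]
    p <- pools[[sid]]
    ok <- length(p$d_ab) + length(p$d_ba) > 0
    row <- tibble::tibble(sample_id = sid, roi_id = "(pooled)",
                          level = "sample",
                          n_a = sum(sub$n_a), n_b = sum(sub$n_b),
                          status = if (ok) "ok" else "insufficient")
    if (config$pooling == "per_sample") {
      row$median_pooled <- if (ok) median(c(p$d_ab, p$d_ba)) else NA_real_
      row$median_a_to_b <- if (length(p$d_ab)) median(p$d_ab) else NA_real_
      row$median_b_to_a <- if (length(p$d_ba)) median(p$d_ba) else NA_real_
    } else {
      okr <- sub$status == "ok"
      row$median_pooled <- if (ok) median(p$roi_medians) else NA_real_
      row$median_a_to_b <- if (any(okr))
        median(sub$median_a_to_b[okr]) else NA_real_
      row$median_b_to_a <- if (any(okr))
        median(sub$median_b_to_a[okr]) else NA_real_
    }
    for (nm in names(p$counts)) {
      v <- p$counts[[nm]]
      row[[paste0("mean_", nm)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("median_", nm)]] <- if (length(v)) median(v) else NA_real_
    }
    row
  })
  out <- dplyr::bind_rows(out, dplyr::bind_rows(pooled_rows))
  out <- out[order(out$sample_id, out$level == "sample", out$roi_id), ]
  attr(out, "config") <- config
  out
}
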