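#' Construct a cell table
#'
#' A cell table holds one row per segmented cell: identifiers
#' (`cell_id`, `sample_id`, `roi_id`), centroid coordinates `x`, `y` in
#' microns, and one column per marker.  Marker values are either
#' continuous intensities (non-negative) or binary positivity calls in
#' \{0, 1\}; the two are never mixed within one table.  Distances are
#' only ever computed between cells of the same ROI.
#'
#' @param df data frame with columns `cell_id`, `sample_id`, `roi_id`,
#'   `x`, `y` plus marker columns.  `sample_id`/`roi_id` are filled with
#'   `"S1"`/`"R1"` when absent.
#' @param markers character vector naming the marker columns.  When
#'   `NULL`, every numeric column other than `x`/`y` and the reserved
#'   columns (`phenotype`, `true_label`, `group`) is taken as a marker.
#' @param marker_type `"auto"` (detect), `"continuous"` or `"binary"`.
#' @param window optional ROI rectangle, either a numeric
#'   `c(xmin, ymin, xmax, ymax)` applied to every ROI or a data frame
#'   with columns `sample_id`, `roi_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @return a `cell_table` (a tibble subclass carrying marker metadata).
#' @export
cell_table <- function(df, markers = NULL,
                       marker_type = c("auto", "continuous", "binary"),
                       window = NULL) {
  marker_type <- match.arg(marker_type)
  df <- tibble::as_tibble(df)
  if (!"sample_id" %in% names(df)) df$sample_id <- "S1"
  if (!"roi_id" %in% names(df)) df$roi_id <- "R1"
  if (is.null(markers)) {
    reserved <- c("cell_id", "sample_id", "roi_id", "x", "y",
                  "phenotype", "true_label", "group")
    cand <- setdiff(names(df), reserved)
    markers <- cand[vapply(df[cand], is.numeric, logical(1))]
  }
  if (marker_type == "auto") {
    all_binary <- length(markers) > 0 &&
      all(vapply(df[markers],
                 function(v) all(v %in% c(0, 1)), logical(1)))
    marker_type <- if (all_binary) "binary" else "continuous"
  }
  x <- structure(df,
                 class = c("cell_table", class(tibble::tibble())),
                 markers = markers,
                 marker_type = marker_type,
                 window = window)
  validate_cell_table(x)
}

#' Validate a cell table
#'
#' Checks the structural invariants: required columns present, finite
#' numeric coordinates, at least one marker with unique names, unique
#' `cell_id` within each (sample, ROI), marker values consistent with the
#' declared type, and containment in the ROI window when one is declared.
#' Malformed input raises an error; rows are never silently dropped.
#'
#' @param x a `cell_table`.
#' @return `x`, invisibly unchanged, when valid.
#' @export
validate_cell_table <- function(x) {
  req <- c("cell_id", "sample_id", "roi_id", "x", "y")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in c("x", "y")) {
    v <- x[[cc]]
    if (!is.numeric(v))
      stop("coordinate column '", cc, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("coordinate column '", cc, "' has non-finite values at row(s) ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  mk <- markers(x)
  if (length(mk) == 0)
    stop("cell table has no marker columns", call. = FALSE)
  if (anyDuplicated(mk))
    stop("duplicated marker names: ",
         paste(unique(mk[duplicated(mk)]), collapse = ", "), call. = FALSE)
  miss_mk <- setdiff(mk, names(x))
  if (length(miss_mk) > 0)
    stop("declared marker column(s) absent: ",
         paste(miss_mk, collapse = ", "), call. = FALSE)
  key <- paste(x$sample_id, x$roi_id, x$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x$cell_id[duplicated(key)]
    stop("duplicate cell_id within a (sample, ROI): ",
         paste(unique(head(d, 5L)), collapse = ", "), call. = FALSE)
  }
  if (marker_type(x) == "binary") {
    for (m in mk) {
      if (!all(x[[m]] %in% c(0, 1)))
        stop("marker '", m, "' declared binary but has values outside {0, 1}",
             call. = FALSE)
    }
  } else {
    for (m in mk) {
      if (!is.numeric(x[[m]]))
        stop("marker '", m, "' is not numeric", call. = FALSE)
    }
  }
  win <- attr(x, "window")
  if (!is.null(win)) {
    if (is.numeric(win) && length(win) == 4) {
      inside <- x$x >= win[1] & x$y >= win[2] & x$x <= win[3] & x$y <= win[4]
      if (!all(inside))
        stop("cells outside the declared window at row(s) ",
             paste(head(which(!inside), 5L), collapse = ", "), call. = FALSE)
    } else if (is.data.frame(win)) {
      for (k in seq_len(nrow(win))) {
        sel <- x$sample_id == win$sample_id[k] & x$roi_id == win$roi_id[k]
        inside <- x$x[sel] >= win$xmin[k] & x$y[sel] >= win$ymin[k] &
          x$x[sel] <= win$xmax[k] & x$y[sel] <= win$ymax[k]
        if (!all(inside))
          stop("cells outside the declared window in ROI ",
               win$roi_id[k], call. = FALSE)
      }
    } else stop("invalid 'window' attribute", call. = FALSE)
  }
  invisible(x)
}

#' Marker metadata accessors
#'
#' @param x a `cell_table`.
#' @return `markers()` the marker column names; `marker_type()` either
#'   `"continuous"` or `"binary"`.
#' @export
markers <- function(x) attr(x, "markers")

#' @rdname markers
#' @export
marker_type <- function(x) attr(x, "marker_type")

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d sample(s), %d ROI(s); markers (%s): %s\n",
              nrow(x), length(unique(x$sample_id)),
              nrow(unique(x[c("sample_id", "roi_id")])),
              marker_type(x), paste(markers(x), collapse = ", ")))
  NextMethod()
}

# dplyr/base subsetting drops our subclass attributes; restore them.
restore_cell_table <- function(df, template) {
  structure(tibble::as_tibble(df),
            class = class(template),
            markers = attr(template, "markers"),
            marker_type = attr(template, "marker_type"),
            window = attr(template, "window"))
}
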