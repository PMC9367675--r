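#' Read a single-cell table from CSV
#'
#' Reads a comma-delimited, headered export of a cell segmentation run
#' (one row per cell) and returns a validated [cell_table()].  Vendor
#' exports use arbitrary column names, so a `schema` maps the required
#' roles onto the file's columns.  Unmapped extra columns are preserved
#' untouched and ignored by the analysis.  Coordinates are taken to be
#' micron centroids in an arbitrary-origin Cartesian plane; only
#' inter-point distances matter downstream.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping roles to file columns.
#'   Recognised roles: `cell_id`, `sample_id`, `roi_id`, `x`, `y`.
#'   Defaults to identity names; `sample_id`/`roi_id` may be absent from
#'   the file, in which case constant ids are filled in.
#' @param markers character vector of marker column names (file names,
#'   kept as-is).  `NULL` takes every remaining numeric column.
#' @param window optional window rectangle, see [cell_table()].
#' @return a validated `cell_table`; row order preserved.
#' @export
read_cell_table <- function(path,
                            schema = c(cell_id = "cell_id",
                                       sample_id = "sample_id",
                                       roi_id = "roi_id",
                                       x = "x", y = "y"),
                            markers = NULL, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  defaults <- c(cell_id = "cell_id", sample_id = "sample_id",
                roi_id = "roi_id", x = "x", y = "y")
  schema <- c(schema, defaults[setdiff(names(defaults), names(schema))])
  optional <- c("sample_id", "roi_id")
  for (role in names(defaults)) {
    col <- schema[[role]]
    if (!col %in% names(raw)) {
      if (role %in% optional) next
      stop("schema error: column '", col, "' (role '", role,
           "') not found in ", path, call. = FALSE)
    }
  }
  df <- tibble::tibble(cell_id = as.character(raw[[schema[["cell_id"]]]]))
  df$sample_id <- if (schema[["sample_id"]] %in% names(raw))
    as.character(raw[[schema[["sample_id"]]]]) else "S1"
  df$roi_id <- if (schema[["roi_id"]] %in% names(raw))
    as.character(raw[[schema[["roi_id"]]]]) else "R1"
  for (role in c("x", "y")) {
    v <- raw[[schema[[role]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad) > 0)
      stop("non-numeric ", role, " coordinate at row(s) ",
           paste(head(bad, 5L), collapse = ", "), " of ", path,
           call. = FALSE)
    df[[role]] <- num
  }
  used <- unname(schema[c("cell_id", "sample_id", "roi_id", "x", "y")])
  rest <- setdiff(names(raw), used)
  for (cc in rest) df[[cc]] <- raw[[cc]]
  cell_table(df, markers = markers, window = window)
}

#' Write a cell table to CSV
#'
#' @param x a `cell_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis result to a delimited-text file
#'
#' All result types serialise to tidy, headered CSV so that re-reading
#' reproduces integer fields bit-for-bit and real fields to the printed
#' precision (15 significant digits).  Degenerate results (for example a
#' proximity result with one phenotype absent) are written as a header
#' plus a single row whose `status` field flags the condition.
#'
#' @param x a [proximity_result][median_cross_distance],
#'   [neighborhood_counts()] result, distance-pair matrix or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.proximity_result <- function(x, path) {
  df <- as_tibble_proximity(x)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.neighborhood_counts <- function(x, path) {
  df <- tibble::tibble(
    center_type = x$center_type %||% NA_character_,
    neighbor_type = x$neighbor_type %||% NA_character_,
    circle_size = x$circle_size,
    size_is_diameter = x$size_is_diameter,
    boundary = x$boundary,
    status = x$status,
    center_id = x$center_ids,
    count = x$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.distance_pair_matrix <- function(x, path) {
  m <- x$values
  df <- data.frame(cell_id = x$row_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("cell_id", x$col_ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path path to a CSV written by [write_results()].
#' @return a tibble.
#' @export
read_results <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE,
                             stringsAsFactors = FALSE))
}

as_tibble_proximity <- function(x) {
  if (x$status != "ok" || (x$n_a + x$n_b) == 0) {
    return(tibble::tibble(status = x$status,
                          direction = NA_character_,
                          cell_id = NA_character_,
                          partner_id = NA_character_,
                          distance = NA_real_))
  }
  tibble::tibble(
    status = "ok",
    direction = c(rep(paste0(x$type_a, "_to_", x$type_b), x$n_a),
                  rep(paste0(x$type_b, "_to_", x$type_a), x$n_b)),
    cell_id = c(x$ids_a, x$ids_b),
    partner_id = c(x$partner_a, x$partner_b),
    distance = c(x$dists_a_to_b, x$dists_b_to_a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
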