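#' Marker rule
#'
#' One positivity/negativity requirement on one marker, optionally with
#' its own intensity threshold (used only when classifying continuous
#' tables).
#'
#' @param marker marker name.
#' @param sense `"positive"` or `"negative"`.
#' @param threshold optional non-negative intensity threshold.
#' @return a `marker_rule` list.
#' @export
marker_rule <- function(marker, sense = c("positive", "negative"),
                        threshold = NULL) {
  sense <- match.arg(sense)
  if (!is.null(threshold) && threshold < 0)
    stop("threshold must be >= 0", call. = FALSE)
  structure(list(marker = marker, sense = sense, threshold = threshold),
            class = "marker_rule")
}

#' Phenotype panel
#'
#' An ordered list of phenotype definitions, each a conjunction of
#' [marker_rule()]s.  Cells are classified by the first phenotype whose
#' rules all hold ("first match wins" — the order is fixed and part of
#' the panel definition); unmatched cells receive `fallback_label`.
#'
#' @param ... named arguments, one per phenotype, each a list of
#'   `marker_rule`s (or a character vector of `"marker+"` / `"marker-"`
#'   tokens, e.g. `c("CD4-", "CD8-", "CD127+", "GATA3+")`).
#' @param fallback_label label for cells matching no phenotype.
#' @return a `phenotype_panel`.
#' @export
phenotype_panel <- function(..., fallback_label = "other") {
  phens <- list(...)
  if (length(phens) == 0) stop("panel needs at least one phenotype",
                               call. = FALSE)
  if (is.null(names(phens)) || any(names(phens) == ""))
    stop("phenotypes must be named", call. = FALSE)
  if (anyDuplicated(names(phens)))
    stop("phenotype labels must be unique", call. = FALSE)
  phens <- lapply(phens, function(p) {
    if (is.character(p)) p <- lapply(p, parse_rule_token)
    if (inherits(p, "marker_rule")) p <- list(p)
    if (length(p) == 0) stop("each phenotype needs >= 1 rule", call. = FALSE)
    stopifnot(all(vapply(p, inherits, logical(1), "marker_rule")))
    p
  })
  structure(list(phenotypes = phens, fallback_label = fallback_label),
            class = "phenotype_panel")
}

parse_rule_token <- function(tok) {
  tok <- trimws(tok)
  sense <- substr(tok, nchar(tok), nchar(tok))
  # accept ASCII +/- and the typographic minus
  if (!sense %in% c("+", "-", "−"))
    stop("cannot parse marker rule token '", tok,
         "' (expected e.g. 'CD4+' or 'CD8-')", call. = FALSE)
  marker_rule(substr(tok, 1, nchar(tok) - 1),
              if (sense == "+") "positive" else "negative")
}

#' The default ILC2/Treg gating panel
#'
#' Tissue gate definitions for the two phenotypes of interest:
#' ILC2 = CD4- CD8- CD127+ GATA3+ and Treg = CD4+ Foxp3+, with fallback
#' `"other"`.  The two gates are mutually exclusive (ILC2 requires CD4-,
#' Treg requires CD4+), so evaluation order does not affect the default
#' panel; it is fixed (ILC2 first) for reproducibility with user panels.
#' Note the tissue Treg gate carries no CD25/CD127-low condition: the
#' imaging panel stains CD4, CD8, CD127, GATA3 and Foxp3 only, unlike
#' flow-cytometry Treg gating.
#'
#' @return a [phenotype_panel()].
#' @export
default_panel <- function() {
  phenotype_panel(
    ILC2 = c("CD4-", "CD8-", "CD127+", "GATA3+"),
    Treg = c("CD4+", "Foxp3+"),
    fallback_label = "other")
}

panel_markers <- function(panel) {
  unique(unlist(lapply(panel$phenotypes,
                       function(p) vapply(p, `[[`, "", "marker"))))
}

#' Read a phenotype panel from a plain-text config block
#'
#' One phenotype per line, `label: marker+ marker- ...`; blank lines and
#' `#` comments ignored.  An optional line `fallback: label` sets the
#' fallback label.
#'
#' @param path file path (or use `text =` for a literal string).
#' @param text literal panel text, overrides `path`.
#' @return a [phenotype_panel()].
#' @export
read_panel <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n")[[1]] else readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  fallback <- "other"
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse panel line: ", ln, call. = FALSE)
    lab <- trimws(parts[1])
    toks <- strsplit(trimws(parts[2]), "[[:space:],]+")[[1]]
    if (identical(tolower(lab), "fallback")) fallback <- toks[1]
    else args[[lab]] <- toks
  }
  do.call(phenotype_panel, c(args, list(fallback_label = fallback)))
}

#' Binarize continuous marker intensities
#'
#' Converts each marker intensity to a positivity call: 1 iff
#' `intensity > threshold` (strict inequality), else 0.  Original
#' intensities are retained alongside in `<marker>_intensity` columns.
#'
#' @param table a continuous `cell_table`.
#' @param thresholds named numeric vector (or list), one threshold per
#'   marker to binarize.  Must cover every marker referenced by any panel
#'   used downstream; see [auto_thresholds()] for a data-driven helper.
#' @return a binary `cell_table`.
#' @export
binarize_markers <- function(table, thresholds) {
  if (marker_type(table) != "continuous")
    stop("table markers are already binary", call. = FALSE)
  thresholds <- unlist(thresholds)
  mk <- intersect(markers(table), names(thresholds))
  if (length(mk) == 0)
    stop("no threshold provided for any marker of the table", call. = FALSE)
  out <- tibble::as_tibble(table)
  for (m in mk) {
    out[[paste0(m, "_intensity")]] <- out[[m]]
    out[[m]] <- as.integer(out[[m]] > thresholds[[m]])
  }
  cell_table(out, markers = mk, marker_type = "binary",
             window = attr(table, "window"))
}

#' Data-driven marker thresholds by bimodal split
#'
#' For each marker, splits the intensities into two groups by 1-d k-means
#' (k = 2) and returns the midpoint between the two group means.  A
#' convenience when per-marker gates are not supplied; inspect the result
#' before trusting it on real data.
#'
#' @param table a continuous `cell_table`.
#' @param which_markers markers to threshold (default: all).
#' @return named numeric vector of thresholds.
#' @export
auto_thresholds <- function(table, which_markers = markers(table)) {
  vapply(which_markers, function(m) {
    v <- table[[m]]
    if (length(unique(v)) < 2) return(max(v))
    km <- kmeans(v, centers = range(v), iter.max = 50)
    mean(range(km$centers))
  }, numeric(1))
}

#' Classify a single cell from binary marker calls
#'
#' @param marker_values named vector of binary calls (0/1 or logical).
#' @param panel a [phenotype_panel()].
#' @return the label of the first phenotype whose rules all hold, else
#'   the panel's fallback label.
#' @export
classify_cell <- function(marker_values, panel = default_panel()) {
  need <- panel_markers(panel)
  miss <- setdiff(need, names(marker_values))
  if (length(miss) > 0)
    stop("configuration error: panel references marker(s) absent from the ",
         "cell: ", paste(miss, collapse = ", "), call. = FALSE)
  for (lab in names(panel$phenotypes)) {
    ok <- all(vapply(panel$phenotypes[[lab]], function(r) {
      pos <- as.logical(marker_values[[r$marker]])
      if (r$sense == "positive") pos else !pos
    }, logical(1)))
    if (ok) return(lab)
  }
  panel$fallback_label
}

#' Classify every cell of a table
#'
#' Vectorised first-match-wins classification.  Each cell receives
#' exactly one label; the per-(sample, ROI, label) counts returned by
#' [phenotype_counts()] partition the table.  Cells matching more than
#' one phenotype (possible under user panels, impossible under the
#' default panel) are counted in the `n_multi_match` attribute.
#'
#' @param table a binary `cell_table` (binarize continuous tables first).
#' @param panel a [phenotype_panel()].
#' @return the table with a `phenotype` column added.
#' @export
classify_table <- function(table, panel = default_panel()) {
  if (marker_type(table) != "binary")
    stop("classify_table needs binary marker calls; run binarize_markers() ",
         "first", call. = FALSE)
  need <- panel_markers(panel)
  miss <- setdiff(need, markers(table))
  if (length(miss) > 0)
    stop("configuration error: panel references marker(s) absent from the ",
         "table: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(table)
  lab <- rep(panel$fallback_label, n)
  n_match <- integer(n)
  for (ph in rev(names(panel$phenotypes))) {
    ok <- rep(TRUE, n)
    for (r in panel$phenotypes[[ph]]) {
      pos <- table[[r$marker]] == 1
      ok <- ok & (if (r$sense == "positive") pos else !pos)
    }
    lab[ok] <- ph           # reverse order => earlier phenotypes overwrite
    n_match <- n_match + ok
  }
  out <- restore_cell_table(table, table)
  out$phenotype <- lab
  attr(out, "n_multi_match") <- sum(n_match > 1)
  out
}

#' Per-(sample, ROI, label) phenotype counts
#'
#' @param table a classified `cell_table` (has a `phenotype` column).
#' @return tibble with columns `sample_id`, `roi_id`, `phenotype`, `n`.
#' @export
phenotype_counts <- function(table) {
  stopifnot("phenotype" %in% names(table))
  dplyr::count(tibble::as_tibble(table),
               .data$sample_id, .data$roi_id, .data$phenotype, name = "n")
}
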