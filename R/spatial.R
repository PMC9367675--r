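# Point-set geometry.  All functions take "point sets": data frames with
# columns cell_id, x, y (a cell_table works; cell_id is generated from the
# row number, zero-padded, when absent).  Distances are Euclidean in the
# plane by default; topology = "torus" wraps distances periodically over a
# rectangular window (used to make closed-form Poisson checks exact).
# Nearest-neighbor ties on exact distance equality are broken towards the
# smallest cell_id in C-locale (radix) order, deterministically across
# platforms.  A candidate carrying the same cell_id as the query cell is
# never its own neighbor.

as_point_set <- function(p, what = "point set") {
  p <- as.data.frame(p)
  if (!all(c("x", "y") %in% names(p)))
    stop(what, " needs 'x' and 'y' columns", call. = FALSE)
  if (!"cell_id" %in% names(p))
    p$cell_id <- sprintf("p%0*d", nchar(nrow(p)) + 1L, seq_len(nrow(p)))
  p$cell_id <- as.character(p$cell_id)
  p[c("cell_id", "x", "y")]
}

torus_periods <- function(topology, window) {
  if (topology != "torus") return(c(0, 0))
  if (is.null(window) || length(window) != 4)
    stop("topology = 'torus' requires window = c(xmin, ymin, xmax, ymax)",
         call. = FALSE)
  c(window[3] - window[1], window[4] - window[2])
}

# squared-distance matrix, identical arithmetic to the C++ path
dist2_matrix <- function(ax, ay, bx, by, torus = FALSE, W = c(0, 0)) {
  dx <- abs(outer(ax, bx, "-"))
  dy <- abs(outer(ay, by, "-"))
  if (torus) {
    dx <- pmin(dx, W[1] - dx)
    dy <- pmin(dy, W[2] - dy)
  }
  dx * dx + dy * dy
}

#' Pairwise distance matrix between two point sets
#'
#' The full matrix of Euclidean distances between every cell of `a` and
#' every cell of `b` — the matrix behind pairwise-distance heatmaps.
#'
#' @param a,b point sets (data frames with `cell_id`, `x`, `y`; a
#'   `cell_table` works).
#' @param topology `"plane"` or `"torus"`.
#' @param window window rectangle `c(xmin, ymin, xmax, ymax)`; required
#'   for the torus.
#' @return a `distance_pair_matrix`: list with `row_ids`, `col_ids` and
#'   the numeric `values` matrix (microns).
#' @export
pairwise_distances <- function(a, b, topology = c("plane", "torus"),
                               window = NULL) {
  topology <- match.arg(topology)
  a <- as_point_set(a, "set A"); b <- as_point_set(b, "set B")
  if (nrow(a) == 0) stop("degenerate input: set A is empty", call. = FALSE)
  if (nrow(b) == 0) stop("degenerate input: set B is empty", call. = FALSE)
  W <- torus_periods(topology, window)
  d2 <- dist2_matrix(a$x, a$y, b$x, b$y, topology == "torus", W)
  structure(list(row_ids = a$cell_id, col_ids = b$cell_id,
                 values = sqrt(d2)),
            class = "distance_pair_matrix")
}

#' Directed nearest-neighbor distances
#'
#' For each cell of `a`, the distance to the nearest cell of `b` and that
#' partner's id.  Not symmetric in `a` and `b`.  A cell appearing in both
#' sets under the same `cell_id` is excluded from its own candidates.
#'
#' @inheritParams pairwise_distances
#' @param method `"grid"` (bucket-grid accelerated search, default) or
#'   `"exhaustive"` (full scan; the reference implementation).  Both
#'   return identical results, including the tie rule.
#' @return tibble with columns `cell_id`, `partner_id`, `distance`, one
#'   row per cell of `a` in input order.
#' @export
directed_nn <- function(a, b, method = c("grid", "exhaustive"),
                        topology = c("plane", "torus"), window = NULL) {
  method <- match.arg(method)
  topology <- match.arg(topology)
  a <- as_point_set(a, "set A"); b <- as_point_set(b, "set B")
  if (nrow(b) == 0) stop("degenerate input: set B is empty", call. = FALSE)
  W <- torus_periods(topology, window)
  lev <- sort(unique(c(a$cell_id, b$cell_id)), method = "radix")
  acode <- match(a$cell_id, lev)
  bcode <- match(b$cell_id, lev)
  if (method == "grid") {
    res <- .nn_grid_cpp(a$x, a$y, acode, b$x, b$y, bcode,
                        topology == "torus", W[1], W[2])
    idx <- res$index
    dd <- res$distance
  } else {
    n <- nrow(a)
    idx <- rep(NA_integer_, n)
    dd <- rep(NA_real_, n)
    chunk <- max(1L, floor(2e6 / max(1L, nrow(b))))
    for (s in seq(1L, n, by = chunk)) {
      rows <- s:min(n, s + chunk - 1L)
      d2 <- dist2_matrix(a$x[rows], a$y[rows], b$x, b$y,
                         topology == "torus", W)
      for (k in seq_along(rows)) {
        di <- d2[k, ]
        di[bcode == acode[rows[k]]] <- Inf
        m <- min(di)
        if (!is.finite(m)) next
        cand <- which(di == m)
        j <- cand[which.min(bcode[cand])]
        idx[rows[k]] <- j
        dd[rows[k]] <- sqrt(m)
      }
    }
  }
  tibble::tibble(cell_id = a$cell_id,
                 partner_id = ifelse(is.na(idx), NA_character_,
                                     b$cell_id[idx]),
                 distance = dd)
}

#' Median cross-type distance between two point sets
#'
#' Measures, for every cell of type A, the distance to its nearest type-B
#' cell, and vice versa, then summarises by the median (midpoint of the
#' two central order statistics for even lengths).  The pooled median is
#' the median of the two concatenated directed vectors; both per-direction
#' medians are always reported as well.
#'
#' @inheritParams directed_nn
#' @param mode which median the `median` field carries: `"pooled"`
#'   (default) or `"per_direction"` (then `median` is `NA` and the two
#'   directional medians stand alone).
#' @param type_a,type_b labels used in printed/serialised output.
#' @return a `proximity_result`: directed distance vectors, nearest
#'   partner ids, the three medians, counts `n_a`/`n_b` and a `status`
#'   flag (`"ok"`, or `"undefined"` when either set is empty — medians
#'   are then `NA`, never a silent zero).
#' @export
median_cross_distance <- function(a, b, mode = c("pooled", "per_direction"),
                                  method = c("grid", "exhaustive"),
                                  topology = c("plane", "torus"),
                                  window = NULL,
                                  type_a = "A", type_b = "B") {
  mode <- match.arg(mode)
  method <- match.arg(method)
  topology <- match.arg(topology)
  a <- as_point_set(a, "set A"); b <- as_point_set(b, "set B")
  res <- list(type_a = type_a, type_b = type_b,
              ids_a = a$cell_id, ids_b = b$cell_id,
              n_a = nrow(a), n_b = nrow(b), median_mode = mode)
  if (nrow(a) == 0 || nrow(b) == 0) {
    res <- c(res, list(dists_a_to_b = numeric(0), dists_b_to_a = numeric(0),
                       partner_a = character(0), partner_b = character(0),
                       median_pooled = NA_real_, median_a_to_b = NA_real_,
                       median_b_to_a = NA_real_, median = NA_real_,
                       status = "undefined"))
    return(structure(res, class = "proximity_result"))
  }
  ab <- directed_nn(a, b, method = method, topology = topology,
                    window = window)
  ba <- directed_nn(b, a, method = method, topology = topology,
                    window = window)
  res$dists_a_to_b <- ab$distance
  res$dists_b_to_a <- ba$distance
  res$partner_a <- ab$partner_id
  res$partner_b <- ba$partner_id
  res$median_a_to_b <- median(ab$distance)
  res$median_b_to_a <- median(ba$distance)
  res$median_pooled <- median(c(ab$distance, ba$distance))
  res$median <- if (mode == "pooled") res$median_pooled else NA_real_
  res$status <- "ok"
  structure(res, class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> %s (n=%d) vs %s (n=%d), status: %s\n",
              x$type_a, x$n_a, x$type_b, x$n_b, x$status))
  if (x$status == "ok")
    cat(sprintf("  median %s->%s: %.3f um | %s->%s: %.3f um | pooled: %.3f um\n",
                x$type_a, x$type_b, x$median_a_to_b,
                x$type_b, x$type_a, x$median_b_to_a, x$median_pooled))
  invisible(x)
}

#' Neighborhood counts within a fixed-size circle
#'
#' For every center cell, the number of neighbor cells within a circle of
#' the stated size.  Following the counting protocol of the assay this
#' reproduces, the size is a *diameter* by default (size 15 um means
#' radius 7.5 um); set `size_is_diameter = FALSE` to pass a radius.  The
#' boundary is inclusive (`distance <= r`) by default.  A cell present in
#' both roles (same `cell_id`) never counts itself.
#'
#' @inheritParams directed_nn
#' @param centers,neighbors point sets.
#' @param size circle size in microns.
#' @param size_is_diameter interpret `size` as a diameter (default).
#' @param boundary `"inclusive"` or `"exclusive"`.
#' @param center_type,neighbor_type labels carried into the result.
#' @return a `neighborhood_counts` object: `center_ids`, integer
#'   `counts`, the circle settings and a `status` flag (`"ok"`, or
#'   `"no_neighbors"` for an empty neighbor set — counts are then all
#'   zero, which is a valid result, not an error).
#' @export
neighborhood_counts <- function(centers, neighbors, size,
                                size_is_diameter = TRUE,
                                boundary = c("inclusive", "exclusive"),
                                method = c("grid", "exhaustive"),
                                topology = c("plane", "torus"),
                                window = NULL,
                                center_type = NULL, neighbor_type = NULL) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  topology <- match.arg(topology)
  if (!is.numeric(size) || length(size) != 1 || size <= 0)
    stop("size must be a single positive number", call. = FALSE)
  centers <- as_point_set(centers, "centers")
  neighbors <- as_point_set(neighbors, "neighbors")
  if (nrow(centers) == 0)
    stop("degenerate input: centers is empty", call. = FALSE)
  r <- if (size_is_diameter) size / 2 else size
  W <- torus_periods(topology, window)
  status <- "ok"
  if (nrow(neighbors) == 0) {
    counts <- integer(nrow(centers))
    status <- "no_neighbors"
  } else {
    lev <- sort(unique(c(centers$cell_id, neighbors$cell_id)),
                method = "radix")
    ccode <- match(centers$cell_id, lev)
    ncode <- match(neighbors$cell_id, lev)
    if (method == "grid") {
      counts <- .count_within_cpp(centers$x, centers$y, ccode,
                                  neighbors$x, neighbors$y, ncode,
                                  r, boundary == "inclusive",
                                  topology == "torus", W[1], W[2])
    } else {
      r2 <- r * r
      counts <- integer(nrow(centers))
      chunk <- max(1L, floor(2e6 / max(1L, nrow(neighbors))))
      for (s in seq(1L, nrow(centers), by = chunk)) {
        rows <- s:min(nrow(centers), s + chunk - 1L)
        d2 <- dist2_matrix(centers$x[rows], centers$y[rows],
                           neighbors$x, neighbors$y,
                           topology == "torus", W)
        for (k in seq_along(rows)) {
          di <- d2[k, ]
          keep <- ncode != ccode[rows[k]]
          counts[rows[k]] <- if (boundary == "inclusive")
            sum(di[keep] <= r2) else sum(di[keep] < r2)
        }
      }
    }
  }
  structure(list(center_ids = centers$cell_id, counts = as.integer(counts),
                 circle_size = size, size_is_diameter = size_is_diameter,
                 boundary = boundary, status = status,
                 center_type = center_type, neighbor_type = neighbor_type),
            class = "neighborhood_counts")
}

#' @export
print.neighborhood_counts <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_counts> %d centers, circle %g um (%s), %s boundary [%s]\n",
    length(x$counts), x$circle_size,
    if (x$size_is_diameter) "diameter" else "radius", x$boundary, x$status))
  cat(sprintf("  mean count %.3f, median %g, max %d\n",
              mean(x$counts), median(x$counts), max(x$counts)))
  invisible(x)
}
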