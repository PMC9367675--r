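# Independent brute-force oracles (plain double loops, no shared code with
# the package's search paths) and small fixture builders.

oracle_d2 <- function(ax, ay, bx, by, torus = FALSE, W = c(0, 0)) {
  dx <- abs(ax - bx); dy <- abs(ay - by)
  if (torus) {
    dx <- min(dx, W[1] - dx)
    dy <- min(dy, W[2] - dy)
  }
  dx * dx + dy * dy
}

# directed NN by exhaustive double loop; ties -> smallest id (radix order)
oracle_nn <- function(a, b, torus = FALSE, W = c(0, 0)) {
  lev <- sort(unique(c(a$cell_id, b$cell_id)), method = "radix")
  out <- data.frame(cell_id = a$cell_id, partner_id = NA_character_,
                    distance = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(a))) {
    best_d2 <- Inf; best_j <- NA_integer_; best_code <- Inf
    for (j in seq_len(nrow(b))) {
      if (b$cell_id[j] == a$cell_id[i]) next
      d2 <- oracle_d2(a$x[i], a$y[i], b$x[j], b$y[j], torus, W)
      code <- match(b$cell_id[j], lev)
      if (d2 < best_d2 || (d2 == best_d2 && code < best_code)) {
        best_d2 <- d2; best_j <- j; best_code <- code
      }
    }
    if (!is.na(best_j)) {
      out$partner_id[i] <- b$cell_id[best_j]
      out$distance[i] <- sqrt(best_d2)
    }
  }
  out
}

oracle_counts <- function(centers, neighbors, r, inclusive = TRUE,
                          torus = FALSE, W = c(0, 0)) {
  cnt <- integer(nrow(centers))
  for (i in seq_len(nrow(centers))) {
    for (j in seq_len(nrow(neighbors))) {
      if (neighbors$cell_id[j] == centers$cell_id[i]) next
      d2 <- oracle_d2(centers$x[i], centers$y[i],
                      neighbors$x[j], neighbors$y[j], torus, W)
      hit <- if (inclusive) d2 <= r * r else d2 < r * r
      if (hit) cnt[i] <- cnt[i] + 1L
    }
  }
  cnt
}

random_point_set <- function(n, prefix, extent = 100, digits = 1) {
  data.frame(cell_id = sprintf("%s%04d", prefix, seq_len(n)),
             x = round(runif(n, 0, extent), digits),
             y = round(runif(n, 0, extent), digits),
             stringsAsFactors = FALSE)
}

# the midpoint gate between the generator's positive and negative marker
# intensity means (10 and 1)
midpoint_thresholds <- function() {
  c(CD4 = 5.5, CD8 = 5.5, CD127 = 5.5, GATA3 = 5.5, Foxp3 = 5.5)
}

classify_synthetic <- function(tab) {
  classify_table(binarize_markers(tab, midpoint_thresholds()))
}

small_cell_csv <- function(path, rows) {
  writeLines(c("cell_id,x,y,CD4,CD8,CD127,GATA3,Foxp3", rows), path)
  path
}
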