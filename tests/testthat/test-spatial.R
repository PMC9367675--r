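test_that("pairwise distances reproduce hand-computed geometry", {
  d <- pairwise_distances(data.frame(cell_id = "a", x = 0, y = 0),
                          data.frame(cell_id = "b", x = 3, y = 4))
  expect_equal(d$values, matrix(5))
  ab <- data.frame(cell_id = c("p", "q"), x = c(0, 1), y = c(0, 0))
  m <- pairwise_distances(ab, ab)$values
  expect_equal(m, matrix(c(0, 1, 1, 0), 2))     # zero diagonal, symmetric
  expect_error(pairwise_distances(ab[0, ], ab), "set A is empty")
})

test_that("pairwise distances match a double-loop recomputation", {
  set.seed(101)
  a <- random_point_set(20, "a")
  b <- random_point_set(30, "b")
  got <- pairwise_distances(a, b)$values
  want <- matrix(0, 20, 30)
  for (i in 1:20) for (j in 1:30)
    want[i, j] <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("directed nearest neighbors honour minima, coincidence and ties", {
  a <- data.frame(cell_id = "a1", x = 0, y = 0)
  b <- data.frame(cell_id = c("b1", "b2"), x = c(3, 10), y = c(4, 0))
  nn <- directed_nn(a, b)
  expect_equal(nn$distance, 5)
  expect_equal(nn$partner_id, "b1")
  # coincident points with distinct ids -> distance 0
  nn0 <- directed_nn(data.frame(cell_id = "a1", x = 1, y = 1),
                     data.frame(cell_id = "b1", x = 1, y = 1))
  expect_equal(nn0$distance, 0)
  # exact tie -> smallest cell_id wins
  tie <- directed_nn(data.frame(cell_id = "q", x = 0, y = 0),
                     data.frame(cell_id = c("b9", "b10"), x = c(2, -2),
                                y = c(0, 0)))
  expect_equal(tie$partner_id, "b10")
  expect_error(directed_nn(a, b[0, ]), "set B is empty")
})

test_that("accelerated and exhaustive searches agree on seeded instances", {
  set.seed(202)
  for (rep in 1:25) {
    a <- random_point_set(sample(5:200, 1), "a")
    b <- random_point_set(sample(5:200, 1), "b")
    topo <- if (rep %% 2) "plane" else "torus"
    W <- if (topo == "torus") c(0, 0, 100, 100) else NULL
    g <- directed_nn(a, b, method = "grid", topology = topo, window = W)
    e <- directed_nn(a, b, method = "exhaustive", topology = topo,
                     window = W)
    expect_identical(g$distance, e$distance)
    expect_identical(g$partner_id, e$partner_id)
  }
  # and both agree with the independent double-loop oracle
  a <- random_point_set(40, "a"); b <- random_point_set(60, "b")
  g <- directed_nn(a, b)
  o <- oracle_nn(a, b)
  expect_identical(g$distance, o$distance)
  expect_identical(g$partner_id, o$partner_id)
})

test_that("a cell appearing in both sets never matches itself", {
  s <- data.frame(cell_id = c("c1", "c2", "c3"), x = c(0, 1, 5), y = 0)
  nn <- directed_nn(s, s)
  expect_equal(nn$partner_id, c("c2", "c1", "c2"))
  expect_equal(nn$distance, c(1, 1, 4))
})

test_that("median cross-distance computes documented order statistics", {
  pr <- median_cross_distance(data.frame(cell_id = "a", x = 0, y = 0),
                              data.frame(cell_id = "b", x = 3, y = 4))
  expect_equal(pr$median_pooled, 5)
  expect_equal(pr$median_a_to_b, 5)
  expect_equal(pr$median_b_to_a, 5)

  a <- data.frame(cell_id = c("a1", "a2"), x = c(0, 100), y = 0)
  b <- data.frame(cell_id = "b1", x = 1, y = 0)
  pr2 <- median_cross_distance(a, b)
  expect_equal(sort(pr2$dists_a_to_b), c(1, 99))
  expect_equal(pr2$dists_b_to_a, 1)
  expect_equal(pr2$median_pooled, 1)            # median of {1, 99, 1}
  expect_true(pr2$median_pooled >= min(c(pr2$dists_a_to_b, pr2$dists_b_to_a)))
  expect_true(pr2$median_pooled <= max(c(pr2$dists_a_to_b, pr2$dists_b_to_a)))

  und <- median_cross_distance(a, b[0, ])
  expect_identical(und$status, "undefined")
  expect_true(is.na(und$median_pooled))         # never a silent zero
})

test_that("neighborhood counts interpret the size as a diameter", {
  ctr <- data.frame(cell_id = "c", x = 0, y = 0)
  nb <- data.frame(cell_id = c("n1", "n2"), x = c(3, 8), y = 0)
  expect_equal(neighborhood_counts(ctr, nb, 15)$counts, 1L)  # r = 7.5
  expect_equal(neighborhood_counts(ctr, nb, 25)$counts, 2L)  # r = 12.5
  expect_equal(neighborhood_counts(ctr, nb, 15,
                                   size_is_diameter = FALSE)$counts, 2L)
  # boundary rule: inclusive counts a cell exactly at the radius
  at_r <- data.frame(cell_id = "n", x = 7.5, y = 0)
  expect_equal(neighborhood_counts(ctr, at_r, 15)$counts, 1L)
  expect_equal(neighborhood_counts(ctr, at_r, 15,
                                   boundary = "exclusive")$counts, 0L)
  # empty neighbor set: zero counts with a status flag, not an error
  z <- neighborhood_counts(ctr, nb[0, ], 15)
  expect_equal(z$counts, 0L)
  expect_identical(z$status, "no_neighbors")
  expect_error(neighborhood_counts(ctr[0, ], nb, 15), "centers is empty")
})

test_that("grid counts equal exhaustive and oracle counts", {
  set.seed(303)
  for (rep in 1:10) {
    ctr <- random_point_set(sample(5:100, 1), "c")
    nb <- random_point_set(sample(5:100, 1), "n")
    topo <- if (rep %% 2) "plane" else "torus"
    W <- if (topo == "torus") c(0, 0, 100, 100) else NULL
    g <- neighborhood_counts(ctr, nb, 20, topology = topo, window = W)
    e <- neighborhood_counts(ctr, nb, 20, method = "exhaustive",
                             topology = topo, window = W)
    expect_identical(g$counts, e$counts)
  }
  ctr <- random_point_set(30, "c"); nb <- random_point_set(40, "n")
  expect_identical(neighborhood_counts(ctr, nb, 18)$counts,
                   oracle_counts(ctr, nb, 9))
})

test_that("counts grow with circle size and respect the partner bound", {
  set.seed(404)
  ctr <- random_point_set(80, "c")
  nb <- random_point_set(120, "n")
  c15 <- neighborhood_counts(ctr, nb, 15)$counts
  c25 <- neighborhood_counts(ctr, nb, 25)$counts
  expect_true(all(c25 >= c15))
  expect_true(all(c25 <= nrow(nb)))
})

test_that("distances scale equivariantly and medians shrink with added points", {
  set.seed(505)
  a <- random_point_set(40, "a")
  b <- random_point_set(50, "b")
  pr <- median_cross_distance(a, b)
  for (cc in c(0.5, 3)) {
    a2 <- a; a2$x <- a$x * cc; a2$y <- a$y * cc
    b2 <- b; b2$x <- b$x * cc; b2$y <- b$y * cc
    pr2 <- median_cross_distance(a2, b2)
    expect_equal(pr2$median_pooled, cc * pr$median_pooled, tolerance = 1e-12)
    expect_identical(
      neighborhood_counts(a2, b2, 15 * cc)$counts,
      neighborhood_counts(a, b, 15)$counts)
  }
  # adding B points can only shrink (or keep) every A->B distance
  extra <- random_point_set(25, "x")
  pr3 <- median_cross_distance(a, rbind(b, extra))
  expect_true(all(pr3$dists_a_to_b <= pr$dists_a_to_b))
  expect_lte(median(pr3$dists_a_to_b), median(pr$dists_a_to_b))
})

test_that("results are invariant to input row order up to the tie rule", {
  set.seed(606)
  a <- random_point_set(30, "a")
  b <- random_point_set(45, "b")
  pa <- sample(nrow(a)); pb <- sample(nrow(b))
  nn1 <- directed_nn(a, b)
  nn2 <- directed_nn(a[pa, ], b[pb, ])
  expect_equal(nn2$distance, nn1$distance[pa])
  expect_equal(nn2$partner_id, nn1$partner_id[pa])
  c1 <- neighborhood_counts(a, b, 20)$counts
  c2 <- neighborhood_counts(a[pa, ], b[pb, ], 20)$counts
  expect_equal(c2, c1[pa])
})

test_that("per-sample summaries pool ROIs and flag degenerate ones", {
  cfg <- synthetic_config(seed = 77)
  tab <- simulate_csr(cfg)
  ct <- classify_synthetic(tab)
  s <- summarize_sample(ct)
  roi <- s[s$level == "roi", ]
  pooled <- s[s$level == "sample", ]
  # single-ROI sample: pooled medians equal the ROI medians
  expect_equal(pooled$median_pooled, roi$median_pooled)
  expect_equal(pooled$mean_count_Treg_around_ILC2_15,
               roi$mean_count_Treg_around_ILC2_15)

  # sample with zero Tregs: undefined medians, flagged, zero cross counts
  solo <- ct[ct$phenotype != "Treg", ]
  solo <- cell_table(tibble::as_tibble(solo), window = attr(ct, "window"))
  expect_message(s2 <- summarize_sample(solo), "insufficient")
  expect_true(all(s2$status == "insufficient"))
  expect_true(all(is.na(s2$median_pooled)))
  expect_equal(s2$mean_count_Treg_around_ILC2_15[s2$level == "roi"], 0)
})

test_that("attraction lowers the pooled median relative to CSR", {
  att <- simulate_tissue(synthetic_config(model = "shared_parent",
                                          sigma = 5, seed = 88))
  csr <- simulate_tissue(synthetic_config(seed = 88))
  ms <- vapply(list(att, csr), function(tab) {
    s <- summarize_sample(classify_synthetic(tab))
    s$median_pooled[s$level == "sample"]
  }, numeric(1))
  expect_lt(ms[1], ms[2])
})
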