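test_that("generators are seed-deterministic", {
  cfg <- synthetic_config(model = "shared_parent", sigma = 10, seed = 17)
  expect_identical(tibble::as_tibble(simulate_shared_parent(cfg)),
                   tibble::as_tibble(simulate_shared_parent(cfg)))
  cfg2 <- synthetic_config(seed = 17)
  expect_identical(tibble::as_tibble(simulate_csr(cfg2)),
                   tibble::as_tibble(simulate_csr(cfg2)))
  coh <- make_cohort(1, 1, 1, n_roi = 2, seed = 23)
  coh2 <- make_cohort(1, 1, 1, n_roi = 2, seed = 23)
  expect_identical(tibble::as_tibble(coh), tibble::as_tibble(coh2))
})

test_that("zero intensity yields no cells and zero window area errors", {
  cfg <- synthetic_config(lambda_a = 0, lambda_b = 1e-4, seed = 3)
  tab <- simulate_csr(cfg)
  expect_equal(sum(tab$true_label == "ILC2"), 0L)
  expect_gt(sum(tab$true_label == "Treg"), 0L)
  expect_error(synthetic_config(window = c(0, 0, 0, 10)), "window")
  expect_error(synthetic_config(model = "shared_parent",
                                parent_intensity = 0), "parent_intensity")
  expect_error(simulate_csr(synthetic_config(model = "shared_parent")),
               "not 'csr'")
})

test_that("CSR counts are Poisson-consistent with the configured intensity", {
  # 100 seeded replicates on a small window; total count ~ Poisson(sum of
  # means), so the standardised total should sit within 3 sd
  lam <- 0.01; area <- 200 * 200
  cfg <- synthetic_config(window = c(0, 0, 200, 200), lambda_a = lam,
                          lambda_b = lam)
  set.seed(41)
  n <- vapply(1:100, function(i) nrow(simulate_csr(cfg)), numeric(1))
  mu <- 2 * lam * area * 100
  expect_lt(abs(sum(n) - mu) / sqrt(mu), 3)
  # positions uniform: mean x near the window centre
  tab <- simulate_csr(synthetic_config(window = c(0, 0, 200, 200),
                                       lambda_a = 0.05, lambda_b = 0.05,
                                       seed = 42))
  expect_lt(abs(mean(tab$x) - 100), 3 * 200 / sqrt(12 * nrow(tab)))
})

test_that("shared-parent intensity matches its configuration in expectation", {
  cfg <- synthetic_config(model = "shared_parent", sigma = 10,
                          lambda_a = 2e-4, lambda_b = 1e-4)
  set.seed(43)
  n_a <- n_b <- 0
  for (i in 1:60) {
    tab <- simulate_shared_parent(cfg)
    n_a <- n_a + sum(tab$true_label == "ILC2")
    n_b <- n_b + sum(tab$true_label == "Treg")
  }
  expect_lt(abs(n_a - 60 * 200) / (60 * 200), 0.15)
  expect_lt(abs(n_b - 60 * 100) / (60 * 100), 0.2)
})

test_that("smaller sigma produces stronger co-location", {
  set.seed(44)
  med_for <- function(sigma, n = 15) {
    cfg <- synthetic_config(model = "shared_parent", sigma = sigma)
    mean(vapply(seq_len(n), function(i) {
      tab <- simulate_shared_parent(cfg)
      A <- tab[tab$true_label == "ILC2", c("cell_id", "x", "y")]
      B <- tab[tab$true_label == "Treg", c("cell_id", "x", "y")]
      median_cross_distance(A, B)$median_pooled
    }, numeric(1)))
  }
  m <- vapply(c(5, 20, 80), med_for, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("marker noise controls phenotype recovery", {
  # noiseless separation: perfect recovery
  cfg <- synthetic_config(marker_noise = list(mean_pos = 10, mean_neg = 1,
                                              sd = 0), seed = 45)
  tab <- simulate_csr(cfg)
  ct <- classify_synthetic(tab)
  expect_equal(mean(ct$phenotype == tab$true_label), 1)
  # degenerate config (no separation) is rejected up front
  expect_error(synthetic_config(marker_noise = list(mean_pos = 1,
                                                    mean_neg = 1, sd = 1)),
               "mean_pos")
  # heavy overlap: pipeline still runs end to end
  cfg2 <- synthetic_config(marker_noise = list(mean_pos = 1.01,
                                               mean_neg = 1, sd = 1),
                           seed = 46)
  ct2 <- classify_synthetic(simulate_csr(cfg2))
  expect_true(all(ct2$phenotype %in% c("ILC2", "Treg", "other")))
})

test_that("ground-truth labels never enter the marker set", {
  tab <- simulate_tissue(synthetic_config(seed = 47))
  expect_false("true_label" %in% markers(tab))
  ct <- classify_synthetic(tab)
  expect_false("true_label" %in% markers(ct))
  coh <- make_cohort(1, 1, 1, n_roi = 1, seed = 48)
  expect_false(any(c("true_label", "group") %in% markers(coh)))
})

test_that("re-drawing marker intensities preserves geometry and labels", {
  tab <- simulate_tissue(synthetic_config(seed = 49))
  cfg <- synthetic_config(marker_noise = list(mean_pos = 50, mean_neg = 0.1,
                                              sd = 0.01))
  tab2 <- attach_marker_intensities(tab, cfg)
  expect_identical(tab2$x, tab$x)
  expect_identical(tab2$true_label, tab$true_label)
  ct <- classify_table(binarize_markers(tab2, setNames(rep(25, 5),
                                                       markers(tab2))))
  expect_equal(mean(ct$phenotype == tab2$true_label), 1)
})

test_that("cohorts carry group metadata and reject empty designs", {
  coh <- make_cohort(2, 1, 1, n_roi = 2, seed = 50)
  expect_setequal(unique(coh$group),
                  c("rejection", "nonrejection", "control"))
  expect_equal(length(unique(coh$sample_id)), 4L)
  expect_equal(length(unique(paste(coh$sample_id, coh$roi_id))), 8L)
  expect_error(make_cohort(0, 0, 0), "empty cohort")
  solo <- make_cohort(1, 0, 0, n_roi = 1, seed = 51)
  expect_equal(unique(solo$group), "rejection")
})
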