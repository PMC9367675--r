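test_that("binarization uses strict inequality against the threshold", {
  df <- data.frame(cell_id = c("a", "b", "c"), x = 1:3, y = 1:3,
                   CD4 = c(5, 3, 0), CD8 = c(0, 0, 0))
  tab <- cell_table(df)
  bt <- binarize_markers(tab, c(CD4 = 3, CD8 = 1))
  expect_equal(bt$CD4, c(1L, 0L, 0L))        # 3.0 at threshold 3.0 -> 0
  expect_equal(bt$CD8, c(0L, 0L, 0L))        # all-zero intensities -> all 0
  expect_equal(bt$CD4_intensity, c(5, 3, 0)) # intensities kept alongside
  expect_equal(marker_type(bt), "binary")
})

test_that("the default panel reproduces the published gates", {
  expect_equal(classify_cell(c(CD4 = 0, CD8 = 0, CD127 = 1, GATA3 = 1,
                               Foxp3 = 0)), "ILC2")
  expect_equal(classify_cell(c(CD4 = 1, CD8 = 0, CD127 = 0, GATA3 = 0,
                               Foxp3 = 1)), "Treg")
  expect_equal(classify_cell(c(CD4 = 0, CD8 = 0, CD127 = 0, GATA3 = 0,
                               Foxp3 = 0)), "other")
})

test_that("all 32 binary marker patterns map to exactly one exclusive label", {
  pats <- expand.grid(CD4 = 0:1, CD8 = 0:1, CD127 = 0:1, GATA3 = 0:1,
                      Foxp3 = 0:1)
  labs <- apply(pats, 1, function(p) classify_cell(p))
  expect_length(labs, 32L)
  want_ilc2 <- pats$CD4 == 0 & pats$CD8 == 0 & pats$CD127 == 1 &
    pats$GATA3 == 1
  want_treg <- pats$CD4 == 1 & pats$Foxp3 == 1
  expect_false(any(want_ilc2 & want_treg))  # gates mutually exclusive
  expect_equal(labs == "ILC2", want_ilc2, ignore_attr = TRUE)
  expect_equal(labs == "Treg", want_treg, ignore_attr = TRUE)
  expect_true(all(labs[!want_ilc2 & !want_treg] == "other"))

  # vectorised classification agrees with the per-cell path
  tab <- cell_table(cbind(data.frame(cell_id = sprintf("p%02d", 1:32),
                                     x = 1:32, y = 1:32), pats),
                    marker_type = "binary")
  ct <- classify_table(tab)
  expect_equal(ct$phenotype, unname(labs))
})

test_that("labels partition the table and are row-order invariant", {
  set.seed(31)
  pats <- data.frame(cell_id = sprintf("c%03d", 1:50), x = runif(50),
                     y = runif(50),
                     CD4 = rbinom(50, 1, .5), CD8 = rbinom(50, 1, .5),
                     CD127 = rbinom(50, 1, .5), GATA3 = rbinom(50, 1, .5),
                     Foxp3 = rbinom(50, 1, .5))
  tab <- cell_table(pats, marker_type = "binary")
  ct <- classify_table(tab)
  counts <- phenotype_counts(ct)
  expect_equal(sum(counts$n), nrow(tab))        # counts partition the table
  perm <- sample(nrow(pats))
  ct2 <- classify_table(cell_table(pats[perm, ], marker_type = "binary"))
  expect_equal(ct2$phenotype, ct$phenotype[perm])
})

test_that("first-match-wins resolves overlapping user panels deterministically", {
  panel1 <- phenotype_panel(Tpos = "CD4+", DP = c("CD4+", "CD8+"))
  panel2 <- phenotype_panel(DP = c("CD4+", "CD8+"), Tpos = "CD4+")
  cellv <- c(CD4 = 1, CD8 = 1)
  expect_equal(classify_cell(cellv, panel1), "Tpos")
  expect_equal(classify_cell(cellv, panel2), "DP")
  tab <- cell_table(data.frame(cell_id = "a", x = 0, y = 0, CD4 = 1,
                               CD8 = 1), marker_type = "binary")
  ct <- classify_table(tab, panel1)
  expect_equal(attr(ct, "n_multi_match"), 1L)   # doublet logged
})

test_that("panels referencing absent markers raise configuration errors", {
  expect_error(classify_cell(c(CD4 = 1), default_panel()), "CD8")
  tab <- cell_table(data.frame(cell_id = "a", x = 0, y = 0, CD4 = 1),
                    marker_type = "binary")
  expect_error(classify_table(tab, default_panel()), "configuration error")
  tab2 <- cell_table(data.frame(cell_id = "a", x = 0, y = 0, CD4 = 2.5))
  expect_error(classify_table(tab2, default_panel()), "binary")
})

test_that("a panel parses from its plain-text specification", {
  p <- read_panel(text = "# gates\nILC2: CD4- CD8- CD127+ GATA3+\n
                          Treg: CD4+ Foxp3+\nfallback: unassigned")
  expect_equal(names(p$phenotypes), c("ILC2", "Treg"))
  expect_equal(p$fallback_label, "unassigned")
  expect_equal(classify_cell(c(CD4 = 0, CD8 = 0, CD127 = 1, GATA3 = 1,
                               Foxp3 = 0), p), "ILC2")
})

test_that("classification of an empty table yields an empty labeled table", {
  tab <- cell_table(data.frame(cell_id = character(0), x = numeric(0),
                               y = numeric(0), CD4 = numeric(0)),
                    markers = "CD4", marker_type = "binary")
  ct <- classify_table(tab, phenotype_panel(Tpos = "CD4+"))
  expect_equal(nrow(ct), 0L)
  expect_equal(nrow(phenotype_counts(ct)), 0L)
})
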