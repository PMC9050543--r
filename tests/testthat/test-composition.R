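test_that("embedding density integrates to 1 and matches the analytic
           density of a standard normal sample", {
  set.seed(31)
  df <- data.frame(umap_1 = rnorm(1e4), umap_2 = rnorm(1e4),
                   condition = "case")
  d <- embedding_density(df, "case", bins = 100)
  dx <- diff(d$x[1:2]); dy <- diff(d$y[1:2])
  expect_lt(abs(sum(d$z) * dx * dy - 1), 1e-6)
  ix <- which.min(abs(d$x)); iy <- which.min(abs(d$y))
  expect_lt(abs(d$z[ix, iy] - dnorm(d$x[ix]) * dnorm(d$y[iy])), 0.02)
})

test_that("duplicating every cell leaves the normalized density unchanged", {
  set.seed(32)
  df <- data.frame(umap_1 = rnorm(200), umap_2 = rnorm(200),
                   condition = "case")
  # fixed kernel: the automatic normal-reference bandwidth shrinks with n
  d1 <- embedding_density(df, "case", bins = 50, bandwidth = c(0.5, 0.5))
  d2 <- embedding_density(rbind(df, df), "case", bins = 50,
                          bandwidth = c(0.5, 0.5))
  expect_equal(d1$z, d2$z, tolerance = 1e-10)
})

test_that("degenerate axis raises a named error", {
  df <- data.frame(umap_1 = rep(1, 20), umap_2 = rnorm(20),
                   condition = "case")
  expect_error(embedding_density(df, "case"), "umap_1")
})

test_that("differential density: identity, ratio rule and antisymmetry", {
  set.seed(33)
  df <- data.frame(umap_1 = rnorm(400), umap_2 = rnorm(400),
                   condition = rep(c("case", "control"), each = 200))
  dc <- embedding_density(df, "case", bins = 40)
  d0 <- embedding_density(df, "control", bins = 40)
  same <- differential_density(dc, dc)
  expect_true(all(same$log2_ratio[!is.na(same$log2_ratio)] == 0))

  dd <- differential_density(dc, d0)
  dd_swap <- differential_density(d0, dc)
  ok <- !is.na(dd$log2_ratio) & !is.na(dd_swap$log2_ratio)
  expect_equal(dd$log2_ratio[ok], -dd_swap$log2_ratio[ok])

  # case = 2 x control pointwise -> exactly 1 bit above the floor
  dc2 <- d0; dc2$z <- 2 * d0$z
  r <- differential_density(dc2, d0, floor = 0)
  pos <- d0$z > 0
  expect_equal(unname(r$log2_ratio[pos]), rep(1, sum(pos)),
               tolerance = 1e-12)
  # grid mismatch
  d0b <- embedding_density(df, "control", bins = 41)
  expect_error(differential_density(dc, d0b), "grid")
})

test_that("proportion test: identity, near-zero-variance and
           exchangeability", {
  tbl <- make_prop_table(c(0.2, 0.2, 0.2, 0.2),
                         rep(c("case", "control"), each = 2))
  r <- proportion_test(tbl, "X")
  expect_equal(r$t, 0); expect_equal(r$p, 1)

  tbl2 <- make_prop_table(c(0.3, 0.3, 0.3, 0.1, 0.1, 0.1),
                          rep(c("case", "control"), each = 3))
  r2 <- proportion_test(tbl2, "X")
  expect_lt(r2$p, 1e-6)
  expect_equal(r2$mean_case, 0.3); expect_equal(r2$mean_control, 0.1)

  # permuting samples within a group leaves the statistic unchanged
  tbl3 <- make_prop_table(c(0.25, 0.31, 0.18, 0.12, 0.09, 0.14),
                          rep(c("case", "control"), each = 3))
  tbl3b <- tbl3[c(3, 1, 2, 5, 6, 4), ]
  class(tbl3b) <- class(tbl3)
  expect_equal(proportion_test(tbl3, "X")$t, proportion_test(tbl3b, "X")$t)
  expect_error(proportion_test(make_prop_table(c(0.1, 0.2, 0.3),
                                               c("case", "control",
                                                 "control")), "X"),
               "2 samples")
})

test_that("beta regression: intercept-only fit on symmetric data recovers
           the sample mean; condition recovery is unbiased", {
  y <- c(0.42, 0.58, 0.45, 0.55, 0.5, 0.38, 0.62, 0.5)
  tbl <- make_prop_table(y, rep(c("case", "control"), 4))
  f <- fit_beta_regression(tbl, "X", covariates = character(0))
  expect_true(f$converged)
  expect_lt(abs(f$fitted[1] - mean(y)), 1e-6)

  set.seed(34)
  est <- replicate(30, {
    cond <- rep(c("control", "case"), each = 20)
    mu <- plogis(-2 + 1 * (cond == "case"))
    yy <- rbeta(40, mu * 50, (1 - mu) * 50)
    fit_beta_regression(make_prop_table(yy, cond),
                        "X", covariates = "condition")$coefficients$estimate[2]
  })
  expect_lt(abs(mean(est) - 1), 0.25)
})

test_that("beta regression handles boundary proportions and flags
           non-convergence honestly", {
  y <- c(0, 0.1, 0.2, 0.05, 0.15, 0.08)
  tbl <- make_prop_table(y, rep(c("case", "control"), 3))
  f <- fit_beta_regression(tbl, "X", covariates = "condition")
  expect_true(all(f$fitted > 0 & f$fitted < 1))
  expect_error(fit_beta_regression(tbl, "nope"), "unknown")
})

test_that("pseudobulk similarity: duplicated types correlate at 1 and the
           correlation matrix is well formed", {
  a <- small_assay(seed = 36, n_cells = 100, n_genes = 200)
  labels <- a$barcode_meta$cell_type
  # plant an exact duplicate type from ODC cells
  dup <- labels
  odc <- which(dup == "ODC")
  half <- odc[seq_len(floor(length(odc) / 2))]
  # duplicate the columns so the two labels have identical pseudobulk
  a2 <- subset_assay(a, barcodes = c(seq_len(ncol(a$counts)), odc))
  lab2 <- c(labels, rep("ODC_copy", length(odc)))
  ps <- pseudobulk_similarity(a2, lab2)
  r <- ps$correlation
  expect_equal(max(abs(r - t(r))), 0)
  expect_equal(unname(diag(r)), rep(1, nrow(r)))
  expect_equal(r["ODC", "ODC_copy"], 1)
  m <- ps$hclust$merge
  first <- sort(abs(m[1, ]))
  expect_setequal(ps$hclust$labels[first],
                  c("ODC", "ODC_copy"))
})

test_that("pseudobulk matches hand-computed Pearson values on a toy", {
  m <- rbind(c(10, 0, 5), c(0, 10, 5), c(5, 5, 5), c(2, 0, 1),
             c(0, 3, 9))
  a <- count_assay(m, data.frame(gene_id = paste0("g", 1:5)),
                   data.frame(barcode = paste0("b", 1:3), sample = "s",
                              cell_type = c("A", "B", "C")))
  ps <- pseudobulk_similarity(a)
  lcpm <- apply(m, 2, function(col) log2(col / sum(col) * 1e6 + 1))
  expect_equal(unname(ps$correlation),
               unname(cor(lcpm)), tolerance = 1e-12)
})

test_that("ROC markers: perfect separation, null gene, and O(n^2) oracle", {
  set.seed(37)
  n_in <- 15; n_out <- 15
  # exclusive_out balances the library sizes so "flat" stays flat after
  # per-cell normalization
  m <- rbind(exclusive = c(rpois(n_in, 20), rep(0, n_out)),
             exclusive_out = c(rep(0, n_in), rpois(n_out, 20)),
             flat = rpois(n_in + n_out, 10),
             noisy = rpois(n_in + n_out, 5))
  a <- count_assay(m, data.frame(gene_id = rownames(m)),
                   data.frame(barcode = paste0("b", seq_len(n_in + n_out)),
                              sample = "s",
                              cell_type = rep(c("T", "rest"),
                                              c(n_in, n_out))))
  sc <- roc_marker_scores(a)
  tsc <- sc[sc$cell_type == "T", ]
  expect_equal(tsc$auc[tsc$gene == "exclusive"], 1)
  expect_lt(abs(tsc$auc[tsc$gene == "flat"] - 0.5), 0.25)

  # pair-counting oracle on the normalized expression
  lib <- colSums(m)
  norm <- t(t(m) / lib * 1e4)
  inset <- seq_len(n_in)
  for (g in rownames(m)) {
    wins <- 0
    for (i in inset) for (j in setdiff(seq_len(n_in + n_out), inset)) {
      wins <- wins + (norm[g, i] > norm[g, j]) +
        0.5 * (norm[g, i] == norm[g, j])
    }
    expect_equal(tsc$auc[tsc$gene == g], unname(wins) / (n_in * n_out),
                 tolerance = 1e-12)
  }
  expect_error(roc_marker_scores(a, labels = rep("T", 30)), "2 labels")
})

test_that("marker filter applies the three strict thresholds", {
  mk <- data.frame(gene = c("a", "b", "c", "d"),
                   cell_type = "T",
                   auc = 1,
                   logfc = c(0.3, 0.25, 0.3, 0.3),
                   pct_in = c(0.6, 0.6, 0.5, 0.6),
                   pct_out = 0,
                   p = 0.001,
                   fdr = c(0.01, 0.01, 0.01, 0.05))
  kept <- filter_markers(mk)
  expect_equal(kept$gene, "a")  # b fails logFC, c fails pct, d fails FDR
  all_in <- filter_markers(mk, max_fdr = 1, min_pct = 0, min_logfc = -Inf)
  expect_equal(nrow(all_in), 4)
})
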