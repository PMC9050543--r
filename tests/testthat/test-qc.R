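test_that("barcode metrics match hand arithmetic and a brute-force oracle", {
  gm <- data.frame(gene_id = c("mt", "g1", "g2", "g3"),
                   is_mito = c(TRUE, FALSE, FALSE, FALSE),
                   is_ribo = c(FALSE, FALSE, TRUE, FALSE))
  m <- matrix(c(5, 15, 0, 0,   # barcode 1: mito 5, g1 15
                0, 0, 0, 0,    # barcode 2: all zero
                2, 1, 4, 3),   # barcode 3
              nrow = 4)
  a <- count_assay(m, gm, data.frame(barcode = c("b1", "b2", "b3"),
                                     sample = "s"))
  expect_warning(met <- compute_barcode_metrics(a), "zero")
  expect_equal(met$umi_total[1], 20)
  expect_equal(met$genes_detected[1], 2)
  expect_equal(met$mito_frac[1], 0.25)
  expect_equal(met$umi_total[2], 0)
  expect_equal(met$mito_frac[2], 0)
  expect_true(met$zero_flag[2])

  # naive double-loop oracle over the dense matrix
  for (j in 1:3) {
    umi <- 0; genes <- 0; mito <- 0; ribo <- 0
    for (i in 1:4) {
      umi <- umi + m[i, j]
      genes <- genes + (m[i, j] > 0)
      if (gm$is_mito[i]) mito <- mito + m[i, j]
      if (gm$is_ribo[i]) ribo <- ribo + m[i, j]
    }
    expect_equal(met$umi_total[j], umi)
    expect_equal(met$genes_detected[j], genes)
    if (umi > 0) {
      expect_equal(met$mito_frac[j], mito / umi)
      expect_equal(met$ribo_frac[j], ribo / umi)
    }
  }
})

test_that("filter_barcodes applies strict inequalities on the toy case", {
  a <- toy_qc_assay()
  res <- filter_barcodes(a, qc_thresholds())
  # (2000,1200,.05,.05,.1) passes; 1500 UMIs, 900 genes, 0.12 mito and
  # 0.2 doublet score each fail their strict bound
  expect_equal(res$assay$barcode_meta$barcode, "b1")
  expect_equal(res$attrition$n_input, 5)
  expect_equal(res$attrition$n_removed, 4)
  expect_equal(res$attrition$n_retained, 1)
  rb <- res$attrition$removed_by
  expect_equal(unname(rb[c("low_umis", "low_genes", "high_mito",
                           "doublet")]), c(1L, 1L, 1L, 1L))
})

test_that("no-op thresholds give the identity filter", {
  a <- small_assay(seed = 2, n_cells = 40, n_genes = 100)
  thr <- qc_thresholds(min_umis = 0, min_genes = 0, max_mito_frac = Inf,
                       max_ribo_frac = Inf, max_doublet_score = Inf)
  res <- filter_barcodes(a, thr)
  expect_equal(ncol(res$assay$counts), ncol(a$counts))
  expect_equal(res$attrition$n_removed, 0)
})

test_that("attrition conservation and filter idempotence hold", {
  a <- small_assay(seed = 4, n_cells = 150, n_genes = 400)
  thr <- qc_thresholds(min_umis = 3000, min_genes = 250,
                       max_mito_frac = 0.08, max_ribo_frac = 0.05)
  res <- filter_barcodes(a, thr)
  at <- res$attrition
  expect_equal(at$n_retained + at$n_removed, at$n_input)
  expect_gte(sum(at$removed_by), at$n_removed)   # overlaps allowed
  expect_true(all(at$removed_by <= at$n_input))
  # idempotence
  res2 <- filter_barcodes(res$assay, thr)
  expect_equal(res2$attrition$n_removed, 0)
  expect_equal(res2$assay$barcode_meta$barcode,
               res$assay$barcode_meta$barcode)
  # order preserved
  expect_true(!is.unsorted(match(res$assay$barcode_meta$barcode,
                                 a$barcode_meta$barcode)))
})

test_that("filter_genes keeps a gene detected in exactly 3 barcodes and
           drops flagged genes regardless of detection", {
  gm <- data.frame(gene_id = c("mt_hi", "g3", "g2", "gempty"),
                   is_mito = c(TRUE, FALSE, FALSE, FALSE),
                   is_ribo = FALSE)
  m <- rbind(c(50, 60, 70, 80),   # mito, detected everywhere -> dropped
             c(1, 1, 1, 0),       # detected in exactly 3 -> kept
             c(1, 1, 0, 0),       # detected in 2 -> dropped
             c(0, 0, 0, 0))       # undetected -> dropped
  a <- count_assay(m, gm, data.frame(barcode = paste0("b", 1:4),
                                     sample = "s"))
  f <- filter_genes(a, qc_thresholds())
  expect_equal(f$gene_meta$gene_id, "g3")
})

test_that("filter_genes on an empty matrix returns an empty matrix", {
  a <- count_assay(matrix(0, 3, 2),
                   data.frame(gene_id = c("a", "b", "c")),
                   data.frame(barcode = c("b1", "b2"), sample = "s"))
  f <- filter_genes(a, qc_thresholds())
  expect_equal(nrow(f$counts), 0L)
  expect_equal(ncol(f$counts), 2L)
})

test_that("doublet scores separate planted doublets and are deterministic", {
  a <- small_assay(seed = 10, n_cells = 200, n_genes = 200,
                   doublet_rate = 0.1)
  s1 <- score_doublets_simple(a, k = 25, n_sim = 400, seed = 3)
  s2 <- score_doublets_simple(a, k = 25, n_sim = 400, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  dbl <- a$barcode_meta$is_doublet
  expect_gt(mean(s1[dbl]), mean(s1[!dbl]))
  expect_equal(score_doublets_simple(a, k = 10, n_sim = 0, seed = 1),
               rep(0, ncol(a$counts)))
  expect_error(score_doublets_simple(a, k = ncol(a$counts), n_sim = 10),
               "smaller")
})
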