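#' QC thresholds for barcode and gene filtering
#'
#' Defaults follow the standard droplet snRNA-seq cascade: barcodes are
#' retained with strictly more than `min_umis` UMIs and `min_genes`
#' detected genes, strictly less than `max_mito_frac` mitochondrial and
#' `max_ribo_frac` ribosomal UMI fraction, and strictly less than
#' `max_doublet_score` doublet score; genes are kept when detected in at
#' least `min_barcodes_per_gene` barcodes (inclusive).
#'
#' @param min_umis exclusive lower bound on per-barcode UMIs (default 1500).
#' @param min_genes exclusive lower bound on detected genes (default 1000).
#' @param max_mito_frac exclusive upper bound on mitochondrial UMI
#'   fraction (default 0.10).
#' @param max_ribo_frac exclusive upper bound on ribosomal UMI fraction
#'   (default 0.10).
#' @param min_barcodes_per_gene inclusive minimum barcodes a gene must be
#'   detected in (default 3).
#' @param max_doublet_score exclusive upper bound on the doublet score
#'   (default 0.15).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umis = 1500, min_genes = 1000,
                          max_mito_frac = 0.10, max_ribo_frac = 0.10,
                          min_barcodes_per_gene = 3,
                          max_doublet_score = 0.15) {
  vals <- c(min_umis, min_genes, max_mito_frac, max_ribo_frac,
            min_barcodes_per_gene, max_doublet_score)
  .sn_assert(all(is.finite(vals) | is.infinite(vals)) && all(vals >= 0),
             "all thresholds must be non-negative")
  structure(list(min_umis = min_umis, min_genes = min_genes,
                 max_mito_frac = max_mito_frac,
                 max_ribo_frac = max_ribo_frac,
                 min_barcodes_per_gene = min_barcodes_per_gene,
                 max_doublet_score = max_doublet_score),
            class = "qc_thresholds")
}

#' Per-barcode QC metrics
#'
#' Computes, for every barcode, the total UMI count, the number of
#' detected genes, and the mitochondrial and ribosomal UMI fractions.
#' Fractions use the raw (pre-filter) per-barcode total as denominator.
#' All-zero barcodes get fractions of 0 and are flagged.
#'
#' @param assay a [count_assay()] with `is_mito`/`is_ribo` gene flags.
#' @return data.frame with columns `barcode`, `umi_total`,
#'   `genes_detected`, `mito_frac`, `ribo_frac`, `zero_flag`.
#' @export
compute_barcode_metrics <- function(assay) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  .sn_assert(all(c("is_mito", "is_ribo") %in% names(assay$gene_meta)),
             "gene_meta must carry is_mito and is_ribo flags")
  m <- assay$counts
  umi <- Matrix::colSums(m)
  genes <- Matrix::colSums(m > 0)
  mito <- Matrix::colSums(m[assay$gene_meta$is_mito, , drop = FALSE])
  ribo <- Matrix::colSums(m[assay$gene_meta$is_ribo, , drop = FALSE])
  zero <- umi == 0
  if (any(zero))
    warning(sum(zero), " barcode(s) with zero total UMIs; ",
            "fractions reported as 0")
  denom <- ifelse(zero, 1, umi)
  data.frame(barcode = assay$barcode_meta$barcode,
             umi_total = as.numeric(umi),
             genes_detected = as.numeric(genes),
             mito_frac = as.numeric(mito / denom),
             ribo_frac = as.numeric(ribo / denom),
             zero_flag = zero, stringsAsFactors = FALSE)
}

#' Filter barcodes by the QC cascade
#'
#' Retains exactly the barcodes passing all criteria (strict inequalities
#' for the UMI, gene, fraction and doublet bounds), preserving barcode
#' order, and reports per-criterion removal counts. When no
#' `doublet_score` column is present that criterion is skipped with a
#' message.
#'
#' @param assay a [count_assay()].
#' @param thr a [qc_thresholds()].
#' @return list with elements `assay` (filtered [count_assay()]) and
#'   `attrition` (a `qc_attrition` report; see [attrition_report()]).
#' @export
filter_barcodes <- function(assay, thr = qc_thresholds()) {
  .sn_assert(inherits(thr, "qc_thresholds"),
             "thr must come from qc_thresholds()")
  met <- suppressWarnings(compute_barcode_metrics(assay))
  crit <- list(low_umis = !(met$umi_total > thr$min_umis),
               low_genes = !(met$genes_detected > thr$min_genes),
               high_mito = !(met$mito_frac < thr$max_mito_frac),
               high_ribo = !(met$ribo_frac < thr$max_ribo_frac))
  if ("doublet_score" %in% names(assay$barcode_meta)) {
    ds <- assay$barcode_meta$doublet_score
    crit$doublet <- !(ds < thr$max_doublet_score) & !is.na(ds)
  } else {
    message("no doublet_score column; doublet criterion skipped")
  }
  removed_any <- Reduce(`|`, crit)
  keep <- !removed_any
  rep <- attrition_report(n_input = nrow(met),
                          removed_by = vapply(crit, sum, 0L),
                          n_removed = sum(removed_any))
  .sn_assert(rep$n_retained == sum(keep), "attrition bookkeeping mismatch")
  list(assay = subset_assay(assay, barcodes = which(keep)),
       attrition = rep)
}

#' Attrition bookkeeping for a filter stage
#'
#' Captures the conservation identity of any filter cascade: with
#' `n_input` barcodes entering and `n_removed` failing at least one
#' criterion, exactly `n_input - n_removed` are retained. Per-criterion
#' counts may overlap, so their sum is at least `n_removed`.
#'
#' @param n_input barcodes entering the stage.
#' @param removed_by named integer vector of per-criterion removal counts,
#'   or a single total when criteria overlap information is unavailable.
#' @param n_removed total removed; defaults to the union size implied by
#'   `removed_by` when that is a single total, otherwise must be supplied
#'   by the caller via `filter_barcodes()`.
#' @return `qc_attrition` list with `n_input`, `removed_by`, `n_removed`,
#'   `n_retained`.
#' @export
attrition_report <- function(n_input, removed_by, n_removed = NULL) {
  .sn_assert(n_input >= 0, "n_input must be non-negative")
  if (is.null(n_removed)) {
    # filter_barcodes passes per-criterion counts and fixes n_removed via
    # the union; standalone use with a single total is the printed-table
    # bookkeeping case.
    n_removed <- if (length(removed_by) == 1L) unname(removed_by)
                 else NA_integer_
  }
  structure(list(n_input = as.numeric(n_input),
                 removed_by = removed_by,
                 n_removed = as.numeric(n_removed),
                 n_retained = as.numeric(n_input) - as.numeric(n_removed)),
            class = "qc_attrition")
}

#' @exportS3Method base::print
print.qc_attrition <- function(x, ...) {
  cat("QC attrition: input", x$n_input, "-> retained", x$n_retained,
      "(removed", x$n_removed, ")\n")
  if (length(x$removed_by) > 1)
    for (nm in names(x$removed_by))
      cat("  ", nm, ":", x$removed_by[[nm]], "\n")
  invisible(x)
}

.sn_attrition_union <- function(crit) Reduce(`|`, crit)

#' Filter genes by detection and flagged groups
#'
#' Drops genes detected in fewer than `min_barcodes_per_gene` barcodes
#' (inclusive rule: a gene detected in exactly the minimum is kept), then
#' removes all mitochondrial and ribosomal genes regardless of detection.
#' Documented order: run after [filter_barcodes()].
#'
#' @param assay a [count_assay()].
#' @param thr a [qc_thresholds()].
#' @return filtered [count_assay()].
#' @export
filter_genes <- function(assay, thr = qc_thresholds()) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  det <- Matrix::rowSums(assay$counts > 0)
  keep <- det >= thr$min_barcodes_per_gene &
    !assay$gene_meta$is_mito & !assay$gene_meta$is_ribo
  subset_assay(assay, genes = which(keep))
}

#' Simple simulation-based doublet score
#'
#' A self-contained stand-in for external doublet callers: simulated
#' doublets are sums of random barcode pairs; each observed barcode is
#' scored by the fraction of simulated doublets among its `k` nearest
#' neighbours in a PCA-reduced log-normalized space.
#'
#' @param assay a [count_assay()].
#' @param k neighbourhood size.
#' @param n_sim number of simulated doublets; 0 gives all-zero scores.
#' @param seed integer seed.
#' @param n_pcs dimensionality of the reduced space.
#' @return numeric vector of scores in `[0, 1]`, one per barcode.
#' @export
score_doublets_simple <- function(assay, k = 25, n_sim = ncol(assay$counts),
                                  seed = 1L, n_pcs = 10) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  n <- ncol(assay$counts)
  .sn_assert(k < n, "k must be smaller than the number of barcodes")
  .sn_assert(n >= 2 * k, "need at least 2k barcodes")
  if (n_sim == 0) return(rep(0, n))
  set.seed(seed)
  i1 <- sample.int(n, n_sim, replace = TRUE)
  i2 <- sample.int(n, n_sim, replace = TRUE)
  sim <- assay$counts[, i1, drop = FALSE] + assay$counts[, i2, drop = FALSE]
  all_counts <- cbind(assay$counts, sim)
  lib <- Matrix::colSums(all_counts)
  lib[lib == 0] <- 1
  norm <- log1p(t(t(as.matrix(all_counts)) / lib * 1e4))
  # top variable genes keep the PCA cheap and informative
  v <- matrixStats::rowVars(norm)
  top <- order(v, decreasing = TRUE)[seq_len(min(500, nrow(norm)))]
  pc <- stats::prcomp(t(norm[top, , drop = FALSE]), rank. = n_pcs,
                      center = TRUE, scale. = FALSE)$x
  d <- as.matrix(dist(pc))
  is_sim <- c(rep(FALSE, n), rep(TRUE, n_sim))
  score <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])[seq_len(k)]
    idx <- seq_len(n + n_sim)[-i][nb]
    score[i] <- mean(is_sim[idx])
  }
  score
}
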