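#' Pseudobulk cell-type similarity
#'
#' Sums counts per cell-type label, normalizes each profile to counts per
#' million, log2(x + 1)-transforms, and computes the Pearson correlation
#' matrix among the type profiles; `1 - r` is fed to average-linkage
#' hierarchical clustering. Labels with zero total counts are excluded
#' with a warning.
#'
#' @param assay a [count_assay()].
#' @param labels per-barcode labels; defaults to
#'   `barcode_meta$cell_type`.
#' @return list with `correlation` (symmetric matrix), `hclust`, and
#'   `pseudobulk` (genes x types log2-CPM matrix).
#' @export
pseudobulk_similarity <- function(assay, labels = NULL) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  if (is.null(labels)) labels <- assay$barcode_meta$cell_type
  .sn_assert(length(labels) == ncol(assay$counts),
             "labels length must match barcode count")
  f <- factor(labels)
  # genes x types sums via sparse indicator multiplication
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  pb <- as.matrix(assay$counts %*% ind)
  colnames(pb) <- levels(f)
  tot <- colSums(pb)
  if (any(tot == 0)) {
    warning("excluding zero-count label(s): ",
            paste(colnames(pb)[tot == 0], collapse = ", "))
    pb <- pb[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  .sn_assert(ncol(pb) >= 2, "need at least 2 non-empty labels")
  lcpm <- log2(t(t(pb) / tot * 1e6) + 1)
  r <- cor(lcpm)
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, hclust = hc, pseudobulk = lcpm)
}

#' Export a pseudobulk dendrogram as Newick
#'
#' @param sim result of [pseudobulk_similarity()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(sim, path) {
  ape::write.tree(ape::as.phylo(sim$hclust), file = path)
  invisible(path)
}

## library-size normalized expression (counts per 10k), dense
.sn_normalized_expr <- function(assay, scale = 1e4) {
  lib <- Matrix::colSums(assay$counts)
  lib[lib == 0] <- 1
  t(t(as.matrix(assay$counts)) / lib * scale)
}

#' One-vs-rest ROC marker scores per (gene, cell type)
#'
#' For each cell type, scores every gene as a one-vs-rest classifier: the
#' AUC of its normalized expression, the log fold-change
#' `log(mean_in + 1) - log(mean_out + 1)` (natural log, pseudocount 1),
#' detection percentages in and out of the type, and a Wilcoxon rank-sum
#' p-value (normal approximation with tie correction),
#' Benjamini-Hochberg-adjusted across genes within each type.
#'
#' @param assay a [count_assay()].
#' @param labels per-barcode labels; defaults to `barcode_meta$cell_type`.
#' @return data.frame with columns `gene`, `cell_type`, `auc`, `logfc`,
#'   `pct_in`, `pct_out`, `p`, `fdr`.
#' @export
roc_marker_scores <- function(assay, labels = NULL) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  if (is.null(labels)) labels <- assay$barcode_meta$cell_type
  f <- factor(labels)
  .sn_assert(nlevels(f) >= 2, "need at least 2 labels")
  norm <- .sn_normalized_expr(assay)
  pos <- norm > 0
  out <- vector("list", nlevels(f))
  for (li in seq_len(nlevels(f))) {
    inset <- f == levels(f)[li]
    n1 <- sum(inset); n2 <- sum(!inset)
    auc <- p <- numeric(nrow(norm))
    for (g in seq_len(nrow(norm))) {
      x <- norm[g, ]
      r <- rank(x)
      R1 <- sum(r[inset])
      U <- R1 - n1 * (n1 + 1) / 2
      auc[g] <- U / (n1 * n2)
      # normal approximation with tie correction
      ties <- table(x)
      tiecor <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
      sU <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tiecor))
      p[g] <- if (sU == 0) 1 else
        2 * pnorm(-abs((U - n1 * n2 / 2) / sU))
    }
    mean_in <- rowMeans(norm[, inset, drop = FALSE])
    mean_out <- rowMeans(norm[, !inset, drop = FALSE])
    out[[li]] <- data.frame(
      gene = rownames(norm), cell_type = levels(f)[li], auc = auc,
      logfc = log(mean_in + 1) - log(mean_out + 1),
      pct_in = rowMeans(pos[, inset, drop = FALSE]),
      pct_out = rowMeans(pos[, !inset, drop = FALSE]),
      p = p, fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter ROC marker scores by the standard thresholds
#'
#' Strict inequalities as conventionally printed: FDR-adjusted p < 0.05,
#' detection percentage within the cluster > 0.5, and logFC > 0.25.
#'
#' @param markers output of [roc_marker_scores()].
#' @param max_fdr,min_pct,min_logfc thresholds.
#' @return filtered data.frame.
#' @export
filter_markers <- function(markers, max_fdr = 0.05, min_pct = 0.5,
                           min_logfc = 0.25) {
  .sn_assert(all(c("fdr", "pct_in", "logfc") %in% names(markers)),
             "markers must come from roc_marker_scores()")
  markers[markers$fdr < max_fdr & markers$pct_in > min_pct &
            markers$logfc > min_logfc, , drop = FALSE]
}
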