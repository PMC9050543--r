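#' Quasi-Poisson differential expression between conditions
#'
#' Per-gene GLM `log E[y] = b0 + b1 * case + log(size_factor)` with a
#' Pearson chi-square dispersion estimate (floored at 1 so standard
#' errors never shrink below Poisson), Wald test on the condition
#' coefficient, and BH q-values. All-zero genes are excluded and listed.
#'
#' @param assay a [count_assay()] with a `condition` column, or a genes x
#'   cells count matrix (then `condition` must be supplied).
#' @param condition optional per-cell `"case"`/`"control"` labels.
#' @param size_factors optional positive per-cell size factors; default
#'   per-cell total counts divided by their geometric mean.
#' @param sample optional per-cell sample labels added as a fixed
#'   covariate.
#' @return data.frame of class `de_result`: `gene`, `coef` (natural-log
#'   case/control fold change), `se`, `p`, `q`, `dispersion`; excluded
#'   all-zero genes in `attr(x, "excluded")`.
#' @export
quasi_poisson_de <- function(assay, condition = NULL, size_factors = NULL,
                             sample = NULL) {
  if (inherits(assay, "count_assay")) {
    m <- as.matrix(assay$counts)
    if (is.null(condition)) condition <- assay$barcode_meta$condition
  } else m <- as.matrix(assay)
  .sn_assert(!is.null(condition) && length(condition) == ncol(m),
             "condition labels required, one per cell")
  .sn_assert(all(c("case", "control") %in% condition),
             "both conditions must be present")
  if (is.null(size_factors)) {
    tot <- colSums(m)
    .sn_assert(all(tot > 0), "cells with zero totals: supply size_factors")
    size_factors <- tot / exp(mean(log(tot)))
  }
  .sn_assert(all(size_factors > 0), "size factors must be positive")
  off <- log(size_factors)
  is_case <- as.numeric(condition == "case")
  X <- cbind(intercept = 1, case = is_case)
  if (!is.null(sample)) {
    f <- factor(sample)
    if (nlevels(f) > 1)
      X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
  }
  nonzero <- rowSums(m) > 0
  excluded <- rownames(m)[!nonzero]
  genes <- which(nonzero)
  res <- data.frame(gene = rownames(m)[genes], coef = NA_real_,
                    se = NA_real_, p = NA_real_, q = NA_real_,
                    dispersion = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    y <- m[genes[i], ]
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = poisson(), offset = off))
    mu <- fit$fitted.values
    dfres <- length(y) - fit$rank
    disp <- max(1, sum((y - mu)^2 / mu) / dfres)
    # Wald SE from the weighted information, scaled by dispersion
    XtWX <- crossprod(X * sqrt(mu))
    vc <- tryCatch(solve(XtWX) * disp, error = function(e) NULL)
    if (is.null(vc)) next
    res$coef[i] <- fit$coefficients["case"]
    res$se[i] <- sqrt(vc["case", "case"])
    res$p[i] <- 2 * pnorm(-abs(res$coef[i] / res$se[i]))
    res$dispersion[i] <- disp
  }
  res$q <- p.adjust(res$p, "BH")
  attr(res, "excluded") <- excluded
  class(res) <- c("de_result", "data.frame")
  res
}

#' Intersect differential expression with trajectory association
#'
#' Genes significant in both analyses with the requested sign of the
#' condition coefficient: `q_de < de_q` and matching direction, and
#' `q_moran < moran_q`. The output is deterministically sorted.
#'
#' @param de a [quasi_poisson_de()] result.
#' @param mi a [morans_i()] result.
#' @param direction `"up"` (coef > 0) or `"down"` (coef < 0).
#' @param de_q,moran_q significance thresholds.
#' @return sorted character vector of gene ids.
#' @export
intersect_de_trajectory <- function(de, mi, direction = c("up", "down"),
                                    de_q = 0.05, moran_q = 0.05) {
  direction <- match.arg(direction)
  .sn_assert(length(intersect(de$gene, mi$gene)) > 0,
             "empty shared gene universe")
  sig_de <- de$gene[!is.na(de$q) & de$q < de_q &
                      (if (direction == "up") de$coef > 0 else de$coef < 0)]
  sig_mi <- mi$gene[!is.na(mi$q) & mi$q < moran_q]
  sort(intersect(sig_de, sig_mi))
}
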