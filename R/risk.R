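#' Convert a one-sided gene association p-value to a z-score
#'
#' `z = qnorm(1 - p)` (upper-tail convention of competitive gene-set
#' regression frameworks).
#'
#' @param p p-values in `(0, 1]`.
#' @return numeric z-scores.
#' @export
p_to_z <- function(p) {
  .sn_assert(all(p > 0 & p <= 1), "p must be in (0, 1]")
  qnorm(p, lower.tail = FALSE)
}

#' Competitive gene-set association test
#'
#' Ordinary least squares of gene z-scores on set membership plus
#' covariates over the whole gene universe:
#' `z_g = alpha + beta * 1[g in set] + gamma' c_g + e`, with a one-sided
#' test of `beta > 0` (enrichment only). The set must be a strict subset
#' of the universe, otherwise there is no competitive contrast.
#'
#' @param z per-gene z-scores (the universe).
#' @param membership logical/0-1 vector: gene in the tested set.
#' @param covariates optional numeric matrix/data.frame of per-gene
#'   covariates (e.g. log gene length, log SNP count).
#' @param conf_level confidence level of the reported interval.
#' @return list of class `set_association`: `beta`, `se`, `p`
#'   (one-sided), `df`, `ci` (two-sided at `conf_level`), `or` =
#'   `exp(beta)` convenience column with its CI, `n_set`, `n_universe`.
#' @export
competitive_set_test <- function(z, membership, covariates = NULL,
                                 conf_level = 0.95) {
  membership <- as.numeric(membership)
  n <- length(z)
  .sn_assert(length(membership) == n, "membership must match z in length")
  k <- sum(membership > 0)
  .sn_assert(k > 0, "empty set")
  .sn_assert(k < n, "set equals the gene universe: no competitive contrast")
  X <- cbind(intercept = 1, set = membership)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    .sn_assert(nrow(cv) == n, "covariates must have one row per gene")
    X <- cbind(X, cv)
  }
  fit <- stats::lm.fit(X, z)
  df <- n - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- unname(fit$coefficients["set"])
  tstat <- beta / se
  p <- pt(tstat, df, lower.tail = FALSE)
  qz <- qt(1 - (1 - conf_level) / 2, df)
  ci <- c(beta - qz * se, beta + qz * se)
  structure(list(beta = beta, se = se, t = tstat, p = p, df = df,
                 ci = ci, or = exp(beta), or_ci = exp(ci),
                 n_set = k, n_universe = n),
            class = "set_association")
}

#' @exportS3Method base::print
print.set_association <- function(x, ...) {
  cat(sprintf(
    "competitive set test: beta = %.4f (se %.4f), one-sided p = %.3g\n",
    x$beta, x$se, x$p))
  cat(sprintf("  set %d of %d genes; 95%% CI [%.4f, %.4f]\n",
              x$n_set, x$n_universe, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Build marker-set membership from marker scores
#'
#' Applies the standard marker filter with strict inequalities
#' (FDR-adjusted p < 0.05, in-cluster detection > 0.5, logFC > 0.25) and
#' returns a genes x cell-types binary membership matrix over the given
#' universe.
#'
#' @param marker_table data.frame with columns `gene`, `cell_type`,
#'   `fdr`, `pct_in`, `logfc` (as from [roc_marker_scores()]).
#' @param universe character vector of gene ids defining the rows;
#'   defaults to the genes present in the table.
#' @param max_fdr,min_pct,min_logfc thresholds.
#' @return binary matrix, rownames = universe, colnames = cell types.
#' @export
marker_sets_from_scores <- function(marker_table, universe = NULL,
                                    max_fdr = 0.05, min_pct = 0.5,
                                    min_logfc = 0.25) {
  need <- c("gene", "cell_type", "fdr", "pct_in", "logfc")
  miss <- setdiff(need, names(marker_table))
  .sn_assert(length(miss) == 0, "marker table misses columns: ",
             paste(miss, collapse = ", "))
  if (is.null(universe)) universe <- sort(unique(marker_table$gene))
  keep <- marker_table$fdr < max_fdr & marker_table$pct_in > min_pct &
    marker_table$logfc > min_logfc
  tab <- marker_table[keep, , drop = FALSE]
  types <- sort(unique(marker_table$cell_type))
  M <- matrix(0L, length(universe), length(types),
              dimnames = list(universe, types))
  hit <- tab$gene %in% universe
  M[cbind(match(tab$gene[hit], universe),
          match(tab$cell_type[hit], types))] <- 1L
  M
}

#' Top contributing genes of a tested set
#'
#' Set genes ranked by association z descending; ties broken
#' lexicographically by gene id.
#'
#' @param z named per-gene z-scores (names = gene ids).
#' @param membership logical/0-1 vector aligned with `z`.
#' @param k how many genes (k larger than the set returns the whole set).
#' @return data.frame `gene`, `z`, `rank`.
#' @export
top_contributors <- function(z, membership, k = 5) {
  .sn_assert(k > 0, "k must be positive")
  .sn_assert(!is.null(names(z)), "z must be named by gene id")
  sel <- which(as.logical(membership))
  ord <- sel[order(-z[sel], names(z)[sel])]
  ord <- head(ord, k)
  data.frame(gene = names(z)[ord], z = unname(z[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
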