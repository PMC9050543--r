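#' Configuration for the gene-statistics simulator
#'
#' Emulates the inputs of competitive gene-set risk enrichment: per-gene
#' association z-scores built from covariate effects (gene length, SNP
#' count) plus a planted mean shift `delta` for genes in enriched sets,
#' with upper-tail p-values consistent with the z-scores.
#'
#' @param n_genes universe size.
#' @param n_sets number of gene sets.
#' @param set_sizes integer vector (recycled) of set sizes.
#' @param enriched_sets integer indices of sets receiving the shift.
#' @param delta planted mean z-shift (>= 0) for enriched-set genes.
#' @param covariate_effects length-2 numeric: coefficients of
#'   standardized log gene length and log SNP count.
#' @param seed integer seed.
#' @return a `sim_gene_stats_config` list.
#' @export
sim_gene_stats_config <- function(n_genes = 10000, n_sets = 10,
                                  set_sizes = 200,
                                  enriched_sets = integer(0),
                                  delta = 0.5,
                                  covariate_effects = c(0.1, 0.1),
                                  seed = 1L) {
  .sn_assert(delta >= 0, "delta must be >= 0")
  .sn_assert(all(set_sizes <= n_genes), "set sizes must be <= n_genes")
  .sn_assert(all(enriched_sets %in% seq_len(n_sets)),
             "enriched_sets must index existing sets")
  structure(list(n_genes = n_genes, n_sets = n_sets,
                 set_sizes = set_sizes, enriched_sets = enriched_sets,
                 delta = delta, covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_gene_stats_config")
}

#' Simulate a gene-statistics table with planted set enrichment
#'
#' `z_g ~ Normal(gamma1 * len_g + gamma2 * snp_g + delta * enriched_g, 1)`
#' with standardized log covariates; `p = P(Z > z)`. Set memberships are
#' sampled independently and may overlap.
#'
#' @param cfg a [sim_gene_stats_config()].
#' @return list of class `gene_stats_table`: `genes` (data.frame `gene`,
#'   `z`, `p`, `log_length`, `log_snps`), `membership` (genes x sets
#'   binary matrix), truth in `attr(x, "truth")`.
#' @export
simulate_gene_stats <- function(cfg) {
  .sn_assert(inherits(cfg, "sim_gene_stats_config"),
             "cfg must come from sim_gene_stats_config()")
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene <- sprintf("RG%05d", seq_len(n))
  log_len <- scale(rnorm(n, 10, 1))[, 1]     # standardized log bp
  log_snp <- scale(0.8 * log_len + rnorm(n, 0, 0.6))[, 1]
  sizes <- rep_len(cfg$set_sizes, cfg$n_sets)
  M <- matrix(0L, n, cfg$n_sets,
              dimnames = list(gene, paste0("set", seq_len(cfg$n_sets))))
  for (s in seq_len(cfg$n_sets)) M[sample.int(n, sizes[s]), s] <- 1L
  shift <- if (length(cfg$enriched_sets))
    cfg$delta * (rowSums(M[, cfg$enriched_sets, drop = FALSE]) > 0)
  else 0
  mu <- cfg$covariate_effects[1] * log_len +
    cfg$covariate_effects[2] * log_snp + shift
  z <- rnorm(n, mu, 1)
  out <- structure(
    list(genes = data.frame(gene = gene, z = z,
                            p = pnorm(z, lower.tail = FALSE),
                            log_length = log_len, log_snps = log_snp,
                            stringsAsFactors = FALSE),
         membership = M),
    class = "gene_stats_table")
  attr(out, "truth") <- list(enriched_sets = cfg$enriched_sets,
                             delta = cfg$delta,
                             covariate_effects = cfg$covariate_effects,
                             seed = cfg$seed)
  out
}
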