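#' Configuration for the case-control count simulator
#'
#' The defaults emulate the structure of a post-mortem midbrain
#' case-control cohort: 11 donors (5 controls, 6 cases), 12 cell types of
#' which one small neuronal cluster is present in case samples only,
#' oligodendrocyte-dominated composition with a glial shift in cases,
#' inter-sample batch variation on the log scale, and a small doublet
#' fraction. Gene panels are scaled down from genome size so the simulator
#' runs in seconds; the statistical structure (negative-binomial
#' overdispersion, marker blocks, mito/ribo gene groups) is preserved.
#'
#' @param n_samples number of donors.
#' @param conditions character vector of length `n_samples`, each
#'   `"control"` or `"case"`.
#' @param n_celltypes total number of cell types including the rare
#'   case-exclusive cluster.
#' @param base_proportions list with elements `control` and `case`, each a
#'   simplex vector of length `n_celltypes - 1` over the non-rare types
#'   (named). `NULL` uses the built-in midbrain-like composition.
#' @param rare_cluster_fraction fraction of cells in each case sample that
#'   belong to the rare case-exclusive cluster; carved out of
#'   `rare_parent`'s share. Must be smaller than the parent proportion.
#' @param rare_parent name of the type the rare cluster is carved from.
#' @param n_genes total gene panel size (includes mito/ribo groups).
#' @param marker_genes_per_type genes upregulated in exactly one type.
#' @param marker_fold fold-change of a marker in its own type.
#' @param batch_sd per-sample log-scale expression shift SD.
#' @param libsize_range 2-vector; singlet library sizes are drawn uniformly
#'   inside this range (doublets are sums of two singlets and may exceed it).
#' @param doublet_rate fraction of barcodes that are doublets.
#' @param nb_dispersion gene-level overdispersion of counts (gamma-weight
#'   parameterisation; 0 gives multinomial sampling).
#' @param n_cells_per_sample singlet barcodes per sample.
#' @param n_mito,n_ribo sizes of the flagged mitochondrial ("MT-") and
#'   ribosomal-protein ("RPS"/"RPL") gene groups.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return a `sim_counts_config` list.
#' @export
sim_counts_config <- function(n_samples = 11,
                              conditions = rep(c("control", "case"),
                                               c(5, 6)),
                              n_celltypes = 12,
                              base_proportions = NULL,
                              rare_cluster_fraction = 0.006,
                              rare_parent = "ExN",
                              n_genes = 1500,
                              marker_genes_per_type = 20,
                              marker_fold = 8,
                              batch_sd = 0.15,
                              libsize_range = c(2000, 12000),
                              doublet_rate = 0.05,
                              nb_dispersion = 0.3,
                              n_cells_per_sample = 400,
                              n_mito = 13, n_ribo = 80,
                              seed = 1L) {
  .sn_assert(length(conditions) == n_samples,
             "conditions must have length n_samples")
  .sn_assert(all(conditions %in% c("control", "case")),
             "conditions must be 'control' or 'case'")
  types <- .sn_default_types(n_celltypes)
  if (is.null(base_proportions))
    base_proportions <- .sn_default_proportions(types$regular)
  for (cond in c("control", "case")) {
    p <- base_proportions[[cond]]
    .sn_assert(!is.null(p) && length(p) == n_celltypes - 1L,
               "base_proportions$", cond, " must have length ",
               n_celltypes - 1L)
    .sn_assert(abs(sum(p) - 1) <= 1e-12,
               "base_proportions for condition '", cond,
               "' does not sum to 1 (sum = ", format(sum(p), digits = 15),
               ")")
  }
  .sn_assert(rare_parent %in% names(base_proportions$case),
             "rare_parent '", rare_parent, "' not among cell types")
  .sn_assert(rare_cluster_fraction >= 0 && rare_cluster_fraction < 1,
             "rare_cluster_fraction must be in [0, 1)")
  .sn_assert(rare_cluster_fraction <
               base_proportions$case[[rare_parent]],
             "rare_cluster_fraction must be below the case proportion of ",
             "its parent type '", rare_parent, "'")
  .sn_assert(length(libsize_range) == 2 && all(libsize_range > 0) &&
               libsize_range[1] <= libsize_range[2],
             "libsize_range must be an increasing pair of positives")
  .sn_assert(doublet_rate >= 0 && doublet_rate < 1,
             "doublet_rate must be in [0, 1)")
  .sn_assert(n_genes - n_mito - n_ribo >=
               n_celltypes * marker_genes_per_type,
             "gene budget too small: n_genes must cover the mito/ribo ",
             "groups plus ", n_celltypes, " x ", marker_genes_per_type,
             " marker genes")
  structure(list(n_samples = n_samples, conditions = conditions,
                 n_celltypes = n_celltypes,
                 base_proportions = base_proportions,
                 rare_cluster_fraction = rare_cluster_fraction,
                 rare_parent = rare_parent, rare_type = types$rare,
                 n_genes = n_genes,
                 marker_genes_per_type = marker_genes_per_type,
                 marker_fold = marker_fold, batch_sd = batch_sd,
                 libsize_range = libsize_range,
                 doublet_rate = doublet_rate,
                 nb_dispersion = nb_dispersion,
                 n_cells_per_sample = n_cells_per_sample,
                 n_mito = n_mito, n_ribo = n_ribo, seed = as.integer(seed)),
            class = "sim_counts_config")
}

.sn_default_types <- function(n_celltypes) {
  base <- c("ODC", "OPC", "Astrocyte", "Microglia", "Ependymal",
            "Endothelial", "Pericyte", "ExN", "InN", "GABA", "DaN")
  n_reg <- n_celltypes - 1L
  .sn_assert(n_reg >= 1, "need at least 2 cell types")
  reg <- if (n_reg <= length(base)) base[seq_len(n_reg)] else
    c(base, paste0("Type", seq_len(n_reg - length(base))))
  list(regular = reg, rare = "CADPS2high")
}

.sn_default_proportions <- function(types) {
  # midbrain-like: oligodendrocytes dominate; cases gain microglia and
  # astrocytes and lose oligodendrocytes; dopaminergic neurons are scarce.
  ctrl <- c(ODC = 0.46, OPC = 0.07, Astrocyte = 0.09, Microglia = 0.07,
            Ependymal = 0.04, Endothelial = 0.04, Pericyte = 0.03,
            ExN = 0.08, InN = 0.06, GABA = 0.055, DaN = 0.005)
  case <- c(ODC = 0.36, OPC = 0.07, Astrocyte = 0.13, Microglia = 0.13,
            Ependymal = 0.04, Endothelial = 0.04, Pericyte = 0.03,
            ExN = 0.08, InN = 0.06, GABA = 0.057, DaN = 0.003)
  ctrl <- ctrl[types]; case <- case[types]
  ctrl[is.na(ctrl)] <- 0.01; case[is.na(case)] <- 0.01
  names(ctrl) <- types; names(case) <- types
  list(control = ctrl / sum(ctrl), case = case / sum(case))
}

#' Simulate a case-control single-nuclei count assay with planted truth
#'
#' Draws per-cell UMI counts from a gamma-weighted multinomial (a
#' Dirichlet-multinomial, i.e. negative-binomial-like overdispersion
#' conditional on an exact library size), with per-type marker blocks,
#' per-sample batch shifts, flagged mitochondrial/ribosomal gene groups, a
#' rare case-exclusive cluster, a 2D Gaussian-mixture embedding per type,
#' and doublets formed as sums of two random singlets.
#'
#' @param cfg a [sim_counts_config()].
#' @return a [count_assay()] whose `barcode_meta` carries the truth columns
#'   `cell_type`, `sample`, `condition`, `age`, `pmi`, `is_doublet`,
#'   `umap_1`, `umap_2`; the planted configuration summary is attached as
#'   `attr(x, "truth")`.
#' @examples
#' a <- simulate_counts(sim_counts_config(n_samples = 2,
#'   conditions = c("control", "case"), n_cells_per_sample = 50,
#'   n_genes = 200, seed = 7))
#' table(a$barcode_meta$condition)
#' @export
simulate_counts <- function(cfg) {
  .sn_assert(inherits(cfg, "sim_counts_config"),
             "cfg must come from sim_counts_config()")
  set.seed(cfg$seed)
  types <- names(cfg$base_proportions$control)
  all_types <- c(types, cfg$rare_type)
  n_types <- length(all_types)

  ## gene panel: mito, ribo, then generic genes; markers for every type
  gene_id <- c(sprintf("MT-G%02d", seq_len(cfg$n_mito)),
               sprintf("RPS%03d", seq_len(ceiling(cfg$n_ribo / 2))),
               sprintf("RPL%03d", seq_len(floor(cfg$n_ribo / 2))),
               sprintf("GENE%05d",
                       seq_len(cfg$n_genes - cfg$n_mito - cfg$n_ribo)))
  .sn_assert(length(gene_id) == cfg$n_genes, "gene bookkeeping error")
  is_mito <- startsWith(gene_id, "MT-")
  is_ribo <- startsWith(gene_id, "RPS") | startsWith(gene_id, "RPL")
  base_rate <- exp(rnorm(cfg$n_genes, 0, 1.2))
  base_rate[is_mito] <- base_rate[is_mito] * 1.5 # nuclei: low mito content
  base_rate[is_ribo] <- base_rate[is_ribo] * 0.5

  generic <- which(!is_mito & !is_ribo)
  .sn_assert(length(generic) >= n_types * cfg$marker_genes_per_type,
             "not enough non-flagged genes for the requested marker blocks")
  marker_idx <- matrix(generic[seq_len(n_types * cfg$marker_genes_per_type)],
                       ncol = n_types)
  colnames(marker_idx) <- all_types
  rate_by_type <- sapply(all_types, function(tt) {
    r <- base_rate
    r[marker_idx[, tt]] <- r[marker_idx[, tt]] * cfg$marker_fold
    r
  })

  ## embedding layout: one Gaussian blob per type on a circle; the rare
  ## cluster sits outside the circle so its region is unambiguous
  ang <- seq(0, 2 * pi, length.out = n_types)[-n_types][seq_len(n_types - 1)]
  centers <- rbind(cbind(10 * cos(ang), 10 * sin(ang)), c(17, 17))
  rownames(centers) <- all_types

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  age <- ifelse(cfg$conditions == "case", rnorm(cfg$n_samples, 77, 5),
                rnorm(cfg$n_samples, 81, 6))
  pmi <- pmax(2, ifelse(cfg$conditions == "case",
                        rnorm(cfg$n_samples, 22, 5),
                        rnorm(cfg$n_samples, 16, 4)))

  blocks <- vector("list", cfg$n_samples)
  meta <- vector("list", cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    cond <- cfg$conditions[s]
    props <- cfg$base_proportions[[cond]]
    props <- c(props, setNames(0, cfg$rare_type))
    if (cond == "case" && cfg$rare_cluster_fraction > 0) {
      props[cfg$rare_type] <- cfg$rare_cluster_fraction
      props[cfg$rare_parent] <- props[cfg$rare_parent] -
        cfg$rare_cluster_fraction
    }
    n_c <- cfg$n_cells_per_sample
    type_of <- sample(all_types, n_c, replace = TRUE, prob = props)
    batch <- rnorm(cfg$n_genes, 0, cfg$batch_sd)
    lib <- round(runif(n_c, cfg$libsize_range[1], cfg$libsize_range[2]))
    m <- matrix(0L, cfg$n_genes, n_c)
    for (i in seq_len(n_c)) {
      r <- rate_by_type[, type_of[i]] * exp(batch)
      if (cfg$nb_dispersion > 0) {
        sh <- 1 / cfg$nb_dispersion
        r <- r * stats::rgamma(cfg$n_genes, shape = sh, rate = sh)
      }
      m[, i] <- rmultinom(1, lib[i], r)
    }
    emb <- centers[type_of, , drop = FALSE] +
      matrix(rnorm(2 * n_c, 0, 0.7), ncol = 2)
    blocks[[s]] <- m
    meta[[s]] <- data.frame(
      barcode = sprintf("%s_BC%05d", samples[s], seq_len(n_c)),
      sample = samples[s], condition = cond, age = age[s], pmi = pmi[s],
      cell_type = type_of, is_doublet = FALSE,
      umap_1 = emb[, 1], umap_2 = emb[, 2], stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  bmeta <- do.call(rbind, meta)

  ## doublets: overwrite a random subset of barcodes with pair sums
  n_total <- ncol(counts)
  n_dbl <- round(cfg$doublet_rate * n_total)
  if (n_dbl > 0) {
    tgt <- sample(n_total, n_dbl)
    partner <- sample(setdiff(seq_len(n_total), tgt), n_dbl,
                      replace = n_total - n_dbl < n_dbl)
    counts[, tgt] <- counts[, tgt] + counts[, partner]
    bmeta$is_doublet[tgt] <- TRUE
    bmeta$umap_1[tgt] <- (bmeta$umap_1[tgt] + bmeta$umap_1[partner]) / 2 +
      rnorm(n_dbl, 0, 0.3)
    bmeta$umap_2[tgt] <- (bmeta$umap_2[tgt] + bmeta$umap_2[partner]) / 2 +
      rnorm(n_dbl, 0, 0.3)
  }

  out <- count_assay(Matrix::Matrix(counts, sparse = TRUE),
                     data.frame(gene_id = gene_id, is_mito = is_mito,
                                is_ribo = is_ribo,
                                stringsAsFactors = FALSE),
                     bmeta)
  attr(out, "truth") <- list(
    base_proportions = cfg$base_proportions, rare_type = cfg$rare_type,
    rare_parent = cfg$rare_parent,
    rare_cluster_fraction = cfg$rare_cluster_fraction,
    rare_center = as.numeric(centers[cfg$rare_type, ]),
    type_centers = centers,
    marker_genes = lapply(seq_len(n_types),
                          function(j) gene_id[marker_idx[, j]]) |>
      setNames(all_types),
    doublet_rate = cfg$doublet_rate, seed = cfg$seed)
  out
}

#' Write simulator ground truth next to a dataset
#'
#' @param x object with a `truth` attribute (any simulator output).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path) {
  tr <- attr(x, "truth")
  .sn_assert(!is.null(tr), "object carries no truth attribute")
  tr <- lapply(tr, function(el) if (is.matrix(el))
    as.data.frame(el) else el)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
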