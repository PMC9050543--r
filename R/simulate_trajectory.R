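#' Configuration for the branched activation-trajectory simulator
#'
#' The defaults emulate a glial activation continuum: a Y-shaped latent
#' tree whose root-side tip is the resting state and whose two remaining
#' tips are activated states, with case cells displaced along pseudotime
#' toward the activated tips, trajectory-modulated genes (monotone or
#' switch-like profiles) and negative-binomial counts.
#'
#' @param n_cells number of cells.
#' @param branch_topology 2-column integer matrix of tree edges over
#'   latent nodes. Default: path 1-2-3 with tips 4 and 5 hanging off
#'   node 3 (a two-branch activation tree).
#' @param node_coords matrix of 2D latent node coordinates, one row per
#'   node.
#' @param root_node latent node the true pseudotime is measured from.
#' @param branch_tip_labels named character vector mapping tip node id
#'   (as character) to a state name; these tips are the designated
#'   activated states.
#' @param condition_shift displacement (in embedding distance units) of
#'   case cells' positions along their root-to-tip path; 0 makes case and
#'   control pseudotime identical in law.
#' @param n_genes,n_trajectory_genes gene panel and planted
#'   trajectory-associated gene count.
#' @param effect_profile `"monotone"`, `"switch"`, or a vector recycled
#'   over trajectory genes.
#' @param effect_size log-scale amplitude of the trajectory effect.
#' @param n_condition_genes genes with a planted case/control fold change
#'   (taken from the start of the trajectory-gene block first, so
#'   DE x trajectory intersections have known truth).
#' @param condition_lfc natural-log fold change (case over control).
#' @param dispersion negative-binomial dispersion (1/size).
#' @param embedding_noise_sd Gaussian jitter of cell embedding positions.
#' @param seed integer seed.
#' @return a `sim_trajectory_config` list.
#' @export
sim_trajectory_config <- function(n_cells = 2000,
                                  branch_topology = rbind(c(1, 2), c(2, 3),
                                                          c(3, 4), c(3, 5)),
                                  node_coords = rbind(c(0, 0), c(4, 0),
                                                      c(8, 0), c(12, 3),
                                                      c(12, -3)),
                                  root_node = 1,
                                  branch_tip_labels = c(`4` = "activated_A",
                                                        `5` = "activated_B"),
                                  condition_shift = 0,
                                  n_genes = 300,
                                  n_trajectory_genes = 60,
                                  effect_profile = c("monotone", "switch"),
                                  effect_size = 1.5,
                                  n_condition_genes = 0,
                                  condition_lfc = 1,
                                  dispersion = 0.5,
                                  embedding_noise_sd = 0.25,
                                  seed = 1L) {
  edges <- as.matrix(branch_topology)
  .sn_assert(ncol(edges) == 2, "branch_topology must be a 2-column matrix")
  nodes <- sort(unique(as.vector(edges)))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  .sn_assert(igraph::is_connected(g) &&
               igraph::ecount(g) == igraph::vcount(g) - 1,
             "branch_topology must be a tree (connected, acyclic)")
  .sn_assert(root_node %in% nodes, "root_node not in the tree")
  .sn_assert(nrow(node_coords) == length(nodes),
             "node_coords must have one row per node")
  tips <- nodes[degree_of(edges, nodes) == 1]
  .sn_assert(all(as.integer(names(branch_tip_labels)) %in% tips),
             "branch_tip_labels keys must be tip nodes")
  .sn_assert(n_trajectory_genes <= n_genes,
             "n_trajectory_genes must not exceed n_genes")
  .sn_assert(n_condition_genes <= n_genes,
             "n_condition_genes must not exceed n_genes")
  structure(list(n_cells = n_cells, branch_topology = edges,
                 node_coords = as.matrix(node_coords),
                 root_node = root_node,
                 branch_tip_labels = branch_tip_labels,
                 condition_shift = condition_shift, n_genes = n_genes,
                 n_trajectory_genes = n_trajectory_genes,
                 effect_profile = effect_profile,
                 effect_size = effect_size,
                 n_condition_genes = n_condition_genes,
                 condition_lfc = condition_lfc,
                 dispersion = dispersion,
                 embedding_noise_sd = embedding_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_trajectory_config")
}

degree_of <- function(edges, nodes) {
  tab <- table(factor(as.vector(edges), levels = nodes))
  as.integer(tab)
}

## path from root to each tip as a node sequence, using the tree edges
.sn_tree_paths <- function(edges, root, tips) {
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  lapply(tips, function(tp) {
    as.integer(names(igraph::shortest_paths(
      g, from = as.character(root), to = as.character(tp))$vpath[[1]]))
  })
}

#' Simulate a branched trajectory count assay with planted truth
#'
#' Cells are placed uniformly along root-to-tip paths of the latent tree;
#' case cells are displaced by `condition_shift` toward the tips. Counts
#' are negative binomial with per-gene means tied to the true pseudotime
#' through monotone or switch-shaped profiles.
#'
#' @param cfg a [sim_trajectory_config()].
#' @return a [count_assay()]; `barcode_meta` carries `pseudotime_true`,
#'   `branch`, `condition`, `umap_1`, `umap_2`; truth (tree, trajectory
#'   and condition gene ids, profiles) in `attr(x, "truth")`.
#' @export
simulate_trajectory <- function(cfg) {
  .sn_assert(inherits(cfg, "sim_trajectory_config"),
             "cfg must come from sim_trajectory_config()")
  set.seed(cfg$seed)
  edges <- cfg$branch_topology
  nodes <- sort(unique(as.vector(edges)))
  coords <- cfg$node_coords
  tips <- nodes[degree_of(edges, nodes) == 1]
  tips <- setdiff(tips, cfg$root_node)
  paths <- .sn_tree_paths(edges, cfg$root_node, tips)
  path_len <- vapply(paths, function(pp) {
    sum(sqrt(rowSums((coords[pp[-1], , drop = FALSE] -
                        coords[pp[-length(pp)], , drop = FALSE])^2)))
  }, 0)

  n <- cfg$n_cells
  condition <- sample(rep(c("control", "case"), length.out = n))
  tip_idx <- sample(length(tips), n, replace = TRUE)
  d <- runif(n) * path_len[tip_idx]
  shift_me <- condition == "case" & cfg$condition_shift != 0
  d[shift_me] <- pmin(d[shift_me] + cfg$condition_shift,
                      path_len[tip_idx[shift_me]])

  ## position each cell along its path; branch = tip state (or "trunk")
  emb <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    pp <- paths[[tip_idx[i]]]
    seg <- coords[pp[-1], , drop = FALSE] -
      coords[pp[-length(pp)], , drop = FALSE]
    seg_len <- sqrt(rowSums(seg^2))
    csum <- cumsum(seg_len)
    j <- which(d[i] <= csum + 1e-12)[1]
    d0 <- if (j == 1) 0 else csum[j - 1]
    frac <- (d[i] - d0) / seg_len[j]
    emb[i, ] <- coords[pp[j], ] + frac * seg[j, ]
  }
  tip_node <- tips[tip_idx]
  branch <- ifelse(
    as.character(tip_node) %in% names(cfg$branch_tip_labels),
    cfg$branch_tip_labels[as.character(tip_node)],
    paste0("tip", tip_node))
  emb <- emb + matrix(rnorm(2 * n, 0, cfg$embedding_noise_sd), ncol = 2)

  ## gene effects along normalized pseudotime
  t_norm <- d / max(path_len)
  gene_id <- sprintf("TG%05d", seq_len(cfg$n_genes))
  profiles <- rep_len(cfg$effect_profile, cfg$n_trajectory_genes)
  beta <- numeric(cfg$n_genes)
  if (cfg$n_trajectory_genes > 0) {
    beta[seq_len(cfg$n_trajectory_genes)] <-
      cfg$effect_size * sample(c(-1, 1), cfg$n_trajectory_genes, TRUE)
  }
  switch_at <- runif(cfg$n_genes, 0.3, 0.7)
  cond_genes <- integer(0)
  if (cfg$n_condition_genes > 0) {
    take <- min(cfg$n_condition_genes, cfg$n_trajectory_genes)
    cond_genes <- seq_len(take)
    if (cfg$n_condition_genes > take)
      cond_genes <- c(cond_genes,
                      cfg$n_trajectory_genes +
                        seq_len(cfg$n_condition_genes - take))
  }
  base_mu <- exp(rnorm(cfg$n_genes, log(2), 0.6))
  libfac <- exp(rnorm(n, 0, 0.2))
  is_case <- condition == "case"
  counts <- matrix(0L, cfg$n_genes, n)
  for (g in seq_len(cfg$n_genes)) {
    shape <- if (g <= cfg$n_trajectory_genes && profiles[g] == "switch")
      1 / (1 + exp(-10 * (t_norm - switch_at[g]))) else t_norm
    eta <- log(base_mu[g]) + beta[g] * shape
    if (g %in% cond_genes) eta <- eta + cfg$condition_lfc * is_case
    counts[g, ] <- rnbinom(n, mu = exp(eta) * libfac,
                           size = 1 / cfg$dispersion)
  }
  out <- count_assay(
    Matrix::Matrix(counts, sparse = TRUE),
    data.frame(gene_id = gene_id, is_mito = FALSE, is_ribo = FALSE,
               stringsAsFactors = FALSE),
    data.frame(barcode = sprintf("TBC%05d", seq_len(n)),
               sample = ifelse(is_case, "case_pool", "control_pool"),
               condition = condition, pseudotime_true = d,
               branch = unname(branch), umap_1 = emb[, 1],
               umap_2 = emb[, 2], stringsAsFactors = FALSE))
  attr(out, "truth") <- list(
    edges = edges, node_coords = coords, root_node = cfg$root_node,
    tips = tips, branch_tip_labels = cfg$branch_tip_labels,
    trajectory_genes = gene_id[seq_len(cfg$n_trajectory_genes)],
    condition_genes = gene_id[cond_genes],
    condition_lfc = cfg$condition_lfc, effect_size = cfg$effect_size,
    condition_shift = cfg$condition_shift, seed = cfg$seed)
  out
}
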