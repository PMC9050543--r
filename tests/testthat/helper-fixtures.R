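# Shared fixtures, built in code. Small scales keep the suite fast; the
# statistical structure matches the generators' stated defaults.

# config with the flagged gene groups and marker panel scaled to a small
# total gene count (the full-scale defaults assume ~1500 genes)
small_cfg <- function(n_genes = 300, n_samples = 4,
                      conditions = c("control", "control", "case",
                                     "case"),
                      n_cells_per_sample = 120, ...) {
  n_mito <- 5
  n_ribo <- max(6, round(0.08 * n_genes))
  markers <- max(3, min(20, floor((n_genes - n_mito - n_ribo) / 24)))
  sim_counts_config(n_samples = n_samples, conditions = conditions,
                    n_cells_per_sample = n_cells_per_sample,
                    n_genes = n_genes, n_mito = n_mito, n_ribo = n_ribo,
                    marker_genes_per_type = markers, ...)
}

small_assay <- function(seed = 1, n_cells = 120, n_genes = 300,
                        doublet_rate = 0.05) {
  simulate_counts(small_cfg(n_genes = n_genes,
                            n_cells_per_sample = n_cells,
                            doublet_rate = doublet_rate, seed = seed))
}

# hand-built assay with exact per-barcode metrics for the QC toy cases
toy_qc_assay <- function() {
  n_genes <- 1300
  gene_meta <- data.frame(
    gene_id = c("MT-1", "RPS1", sprintf("G%04d", seq_len(n_genes - 2))),
    is_mito = c(TRUE, rep(FALSE, n_genes - 1)),
    is_ribo = c(FALSE, TRUE, rep(FALSE, n_genes - 2)))
  # target (umi, genes, mito, ribo): see test for expected pass/fail
  build_col <- function(umi, genes, mito_frac, ribo_frac) {
    col <- numeric(n_genes)
    col[1] <- round(mito_frac * umi)
    col[2] <- round(ribo_frac * umi)
    n_extra <- genes - 3          # gene 3 absorbs the remainder
    col[4:(3 + n_extra)] <- 1
    col[3] <- umi - sum(col)
    col
  }
  m <- cbind(build_col(2000, 1200, 0.05, 0.05),
             build_col(1500, 1200, 0.05, 0.05),
             build_col(2000, 900, 0.05, 0.05),
             build_col(2000, 1200, 0.12, 0.05),
             build_col(2000, 1200, 0.05, 0.05))
  count_assay(m, gene_meta,
              data.frame(barcode = paste0("b", 1:5), sample = "s1",
                         doublet_score = c(0.1, 0.1, 0.1, 0.1, 0.2)))
}

# manual proportion_table for regression tests
make_prop_table <- function(proportion, condition,
                            sample = sprintf("s%02d", seq_along(proportion)),
                            cell_type = "X", ...) {
  tbl <- data.frame(sample = sample, cell_type = cell_type, count = 1,
                    proportion = proportion, condition = condition, ...)
  class(tbl) <- c("proportion_table", "data.frame")
  tbl
}

# rasterized disc (pixel-centre rule), the rasterization oracle
disc_mask <- function(h, w, cx, cy, r) {
  gx <- matrix(seq_len(w), h, w, byrow = TRUE)
  gy <- matrix(seq_len(h), h, w)
  (gx - cx)^2 + (gy - cy)^2 <= r^2
}

# brute-force Moran's I (double loop)
moran_oracle <- function(W, x) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * xc[i] * xc[j]
  (n / sum(W)) * num / sum(xc^2)
}

# brute-force per-pixel branch/endpoint oracle on a skeleton: counts
# circular 0->1 transitions in the 8-neighbour ring (double loop)
crossing_oracle <- function(sk) {
  offs <- list(c(1, 0), c(1, -1), c(0, -1), c(-1, -1), c(-1, 0),
               c(-1, 1), c(0, 1), c(1, 1))  # P2..P9 clockwise from north
  bp <- 0; ep <- 0
  for (y in seq_len(nrow(sk))) for (x in seq_len(ncol(sk))) {
    if (!sk[y, x]) next
    vals <- vapply(offs, function(o) {
      yy <- y - o[1]; xx <- x - o[2]
      yy >= 1 && yy <= nrow(sk) && xx >= 1 && xx <= ncol(sk) &&
        sk[yy, xx]
    }, TRUE)
    ring <- c(vals, vals[1])
    cn <- sum(!ring[-9] & ring[-1])
    if (cn >= 3) bp <- bp + 1
    if (cn == 1) ep <- ep + 1
  }
  c(bp, ep)
}

# brute-force Dijkstra over a weighted edge list
dijkstra_oracle <- function(n_nodes, edges, from) {
  d <- rep(Inf, n_nodes)
  d[from] <- 0
  visited <- rep(FALSE, n_nodes)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges$from[e]; v <- edges$to[e]; w <- edges$length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  repeat {
    cand <- which(!visited & is.finite(d))
    if (length(cand) == 0) break
    u <- cand[which.min(d[cand])]
    visited[u] <- TRUE
    if (!is.null(adj[[u]]))
      for (k in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][k, 1]; w <- adj[[u]][k, 2]
        if (d[u] + w < d[v]) d[v] <- d[u] + w
      }
  }
  d
}
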