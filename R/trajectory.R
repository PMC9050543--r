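#' Learn a principal graph (k-means + MST surrogate)
#'
#' Places `n_centroids` k-means centroids in the 2D embedding and joins
#' them with a Euclidean minimum spanning tree; each cell is projected to
#' the nearest point on the nearest tree edge. This is a documented
#' surrogate for elastic principal-graph methods: downstream rooting,
#' pseudotime and density operations depend only on a tree plus
#' projections, and topology-recovery tests guard its adequacy.
#'
#' @param cells a [count_assay()] with `umap_1`/`umap_2`, or an n x 2
#'   coordinate matrix.
#' @param n_centroids number of graph nodes (>= 2).
#' @param seed integer seed for k-means.
#' @return object of class `trajectory_graph`: `nodes` (k x 2), `edges`
#'   (data.frame `from`, `to`, `length`), `cell_assignment` (data.frame
#'   `edge`, `t`, `dist`, `x`, `y`), `root = NA`, `pseudotime = NULL`.
#' @export
learn_principal_graph <- function(cells, n_centroids, seed = 1L) {
  emb <- if (inherits(cells, "count_assay"))
    cbind(cells$barcode_meta$umap_1, cells$barcode_meta$umap_2)
  else as.matrix(cells)
  .sn_assert(ncol(emb) == 2, "embedding must be 2D")
  .sn_assert(n_centroids >= 2, "n_centroids must be >= 2")
  .sn_assert(nrow(emb) >= n_centroids,
             "need at least n_centroids cells")
  set.seed(seed)
  km <- kmeans(emb, centers = n_centroids, nstart = 10, iter.max = 100)
  cen <- km$centers
  dup <- duplicated(round(cen, 10))
  if (any(dup)) {
    warning("duplicate centroids jittered")
    cen[dup, ] <- cen[dup, ] + rnorm(2 * sum(dup), 0, 1e-6)
  }
  dmat <- as.matrix(dist(cen))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      length = igraph::E(mst)$weight)
  out <- structure(list(nodes = unname(cen), edges = edges,
                        cell_assignment = NULL, root = NA_integer_,
                        pseudotime = NULL),
                   class = "trajectory_graph")
  out$cell_assignment <- .sn_project_cells(out, emb)
  out
}

## project points onto the nearest point of the nearest edge
.sn_project_cells <- function(g, emb) {
  n <- nrow(emb)
  best <- data.frame(edge = rep(NA_integer_, n), t = NA_real_,
                     dist = Inf, x = NA_real_, y = NA_real_)
  for (e in seq_len(nrow(g$edges))) {
    a <- g$nodes[g$edges$from[e], ]
    b <- g$nodes[g$edges$to[e], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((emb[, 1] - a[1]) * ab[1] + (emb[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- sqrt((emb[, 1] - px)^2 + (emb[, 2] - py)^2)
    upd <- d < best$dist
    best$edge[upd] <- e; best$t[upd] <- t[upd]; best$dist[upd] <- d[upd]
    best$x[upd] <- px[upd]; best$y[upd] <- py[upd]
  }
  best
}

## weighted geodesic node-to-node distance matrix of the tree
.sn_node_distances <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g$nodes))))
  igraph::distances(ig, weights = g$edges$length)
}

#' Root a trajectory graph away from the activated subpopulation
#'
#' Supervised rooting rule: the root is the graph node maximizing the
#' minimum geodesic distance to the set of nodes nearest to the known
#' activated cells (maximin; ties broken by lowest node id). Pseudotime is
#' then the geodesic distance from the root to each cell's projection.
#'
#' @param g a [learn_principal_graph()] result.
#' @param activated_cells integer or logical index of the activated cells
#'   among the projected cells.
#' @return `g` with `root` set and `pseudotime` filled (one value per
#'   cell).
#' @export
root_supervised <- function(g, activated_cells) {
  .sn_assert(inherits(g, "trajectory_graph"),
             "g must be a trajectory_graph")
  ca <- g$cell_assignment
  .sn_assert(!is.null(ca), "graph has no cell projections")
  if (is.logical(activated_cells)) activated_cells <- which(activated_cells)
  .sn_assert(length(activated_cells) > 0, "activated_cells is empty")
  D <- .sn_node_distances(g)
  .sn_assert(all(is.finite(D)), "graph must be connected")
  ## node nearest each activated cell: closer endpoint of its edge
  e <- ca$edge[activated_cells]; t <- ca$t[activated_cells]
  len <- g$edges$length[e]
  near_node <- ifelse(t * len <= (1 - t) * len,
                      g$edges$from[e], g$edges$to[e])
  A <- unique(near_node)
  score <- apply(D[, A, drop = FALSE], 1, min)
  root <- unname(which(score == max(score))[1])  # ties -> lowest node id
  g$root <- root
  via_from <- D[root, g$edges$from[ca$edge]] + ca$t * g$edges$length[ca$edge]
  via_to <- D[root, g$edges$to[ca$edge]] +
    (1 - ca$t) * g$edges$length[ca$edge]
  g$pseudotime <- unname(pmin(via_from, via_to))
  g
}

#' @exportS3Method base::print
print.trajectory_graph <- function(x, ...) {
  cat("trajectory_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges")
  if (!is.na(x$root)) cat(", rooted at node", x$root)
  cat("\n")
  invisible(x)
}

#' Pseudotime density contrast between conditions
#'
#' Gaussian kernel densities of pseudotime for case and control cells on a
#' shared grid (common bandwidth: mean of the per-condition
#' normal-reference bandwidths), with their difference (case - control).
#'
#' @param g a rooted [trajectory_graph] (or numeric pseudotime vector).
#' @param conditions per-cell condition labels (`"case"`/`"control"`).
#' @param n_grid grid resolution.
#' @return list with `grid`, `density_case`, `density_control`,
#'   `difference`, `mean_case`, `mean_control`.
#' @export
pseudotime_density_contrast <- function(g, conditions, n_grid = 512) {
  pt <- if (inherits(g, "trajectory_graph")) g$pseudotime else g
  .sn_assert(!is.null(pt), "graph is not rooted (no pseudotime)")
  .sn_assert(length(conditions) == length(pt),
             "conditions must have one label per cell")
  x1 <- pt[conditions == "case"]; x0 <- pt[conditions == "control"]
  .sn_assert(length(x1) >= 10 && length(x0) >= 10,
             "need at least 10 cells per condition")
  .sn_assert(sd(pt) > 0, "zero-variance pseudotime")
  bw <- mean(c(stats::bw.nrd0(x1), stats::bw.nrd0(x0)))
  # extend past the data range so each density integrates to ~1 on-grid
  lim <- range(pt) + c(-3, 3) * bw
  d1 <- density(x1, bw = bw, from = lim[1], to = lim[2], n = n_grid)
  d0 <- density(x0, bw = bw, from = lim[1], to = lim[2], n = n_grid)
  list(grid = d1$x, density_case = d1$y, density_control = d0$y,
       difference = d1$y - d0$y,
       mean_case = mean(x1), mean_control = mean(x0))
}

#' Serialize a trajectory graph to JSON
#'
#' @param g trajectory_graph.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(g, path) {
  .sn_assert(inherits(g, "trajectory_graph"),
             "g must be a trajectory_graph")
  jsonlite::write_json(
    list(nodes = as.data.frame(g$nodes), edges = g$edges,
         root = g$root, pseudotime = g$pseudotime),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
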