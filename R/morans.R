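#' k-nearest-neighbour spatial weight matrix
#'
#' Builds the weight graph used for Moran's I on a cell embedding: kNN
#' adjacency (excluding self), row-standardized, then symmetrized by
#' averaging with its transpose.
#'
#' @param emb n x d coordinate matrix.
#' @param k neighbours per cell (default 15).
#' @return dense n x n weight matrix.
#' @export
knn_weight_matrix <- function(emb, k = 15) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  .sn_assert(k >= 1 && k < n, "k must be in [1, n)")
  d <- as.matrix(dist(emb))
  diag(d) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(d[i, ])[seq_len(k)]] <- 1
  W <- W / rowSums(W)
  (W + t(W)) / 2
}

#' Moran's I spatial autocorrelation per gene
#'
#' For each gene x on a weight graph W:
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' with z-score and one-sided (greater) p-value from the normal
#' approximation under the randomization assumption, and BH adjustment
#' across genes. Constant genes are flagged as undefined, never silently
#' zero.
#'
#' @param W n x n weight matrix (e.g. [knn_weight_matrix()]).
#' @param expr genes x cells matrix (or a single numeric vector).
#' @return data.frame of class `moran_result`: `gene`, `I`,
#'   `expectation`, `z`, `p`, `q`, `flagged`.
#' @export
morans_i <- function(W, expr) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  expr <- as.matrix(expr)
  .sn_assert(ncol(expr) == n, "expression must have one column per cell")
  S0 <- sum(W)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  EI <- -1 / (n - 1)
  xc <- expr - rowMeans(expr)
  denom <- rowSums(xc^2)
  num <- rowSums((xc %*% W) * xc)
  I <- (n / S0) * num / denom
  b2 <- n * rowSums(xc^4) / denom^2
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  z <- (I - EI) / sqrt(varI)
  p <- pnorm(z, lower.tail = FALSE)
  flagged <- denom == 0
  I[flagged] <- NA_real_; z[flagged] <- NA_real_; p[flagged] <- NA_real_
  gn <- rownames(expr)
  if (is.null(gn)) gn <- paste0("gene", seq_len(nrow(expr)))
  res <- data.frame(gene = gn, I = I, expectation = EI, z = z, p = p,
                    q = p.adjust(p, "BH"), flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("moran_result", "data.frame")
  res
}
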