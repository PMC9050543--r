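#' Loess mean-variance normalization
#'
#' Fits a loess curve of per-gene variance on per-gene mean of the
#' log1p-transformed counts, then centres each gene by its mean and
#' scales by the square root of its fitted variance. Zero-variance genes
#' come out as all zeros and are flagged.
#'
#' @param assay a [count_assay()] or a genes x cells matrix of counts.
#' @param span loess span.
#' @return genes x cells normalized matrix; flagged gene ids in
#'   `attr(x, "zero_variance")`.
#' @export
loess_normalize <- function(assay, span = 0.5) {
  m <- if (inherits(assay, "count_assay")) as.matrix(assay$counts)
       else as.matrix(assay)
  lg <- log1p(m)
  mu <- rowMeans(lg)
  v <- matrixStats::rowVars(lg)
  const <- v == 0
  fitted_v <- rep(NA_real_, nrow(lg))
  if (sum(!const) > 3) {
    fit <- loess(v[!const] ~ mu[!const], span = span, degree = 2)
    fitted_v[!const] <- pmax(predict(fit), 1e-8)
  } else {
    fitted_v[!const] <- v[!const]
  }
  out <- (lg - mu) / sqrt(ifelse(const, 1, fitted_v))
  out[const, ] <- 0
  attr(out, "zero_variance") <- rownames(m)[const]
  out
}

## truncated SVD projection: fit on train, apply to test (no centring,
## mirroring the sparse-friendly convention)
.sn_truncated_svd <- function(train, n_components) {
  k <- min(n_components, dim(train) - 0L)
  sv <- svd(train, nu = 0, nv = min(n_components, ncol(train)))
  sv$v[, seq_len(min(n_components, ncol(sv$v))), drop = FALSE]
}

## plain kNN classifier on a Euclidean space
.sn_knn_predict <- function(train_x, train_y, test_x, k = 15) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rep(1, nrow(train_x))) +
    outer(rep(1, nrow(test_x)), rowSums(train_x^2)) -
    2 * test_x %*% t(train_x)
  apply(d2, 1, function(di) {
    nb <- train_y[order(di)[seq_len(k)]]
    names(which.max(table(nb)))
  })
}

#' Cross-validation configuration
#'
#' @param n_folds number of repeats (or folds in strict mode).
#' @param train_frac training fraction for repeated stratified splits.
#' @param n_components truncated-SVD dimensionality.
#' @param subsample_to per-class cap; `"median"` caps every class at the
#'   median class size, `NULL` disables subsampling.
#' @param classifier `"knn"` (default; self-contained) or
#'   `"multinomial"` (ridge multinomial via glmnet when available).
#' @param strict_kfold use disjoint stratified k-folds instead of
#'   repeated 70/30 splits.
#' @param knn_k neighbours for the kNN classifier.
#' @param loess_span span of the mean-variance normalization.
#' @param seed integer seed.
#' @return a `cv_config` list.
#' @export
cv_config <- function(n_folds = 5, train_frac = 0.7, n_components = 30,
                      subsample_to = "median",
                      classifier = c("knn", "multinomial"),
                      strict_kfold = FALSE, knn_k = 15,
                      loess_span = 0.5, seed = 1L) {
  .sn_assert(train_frac > 0 && train_frac < 1,
             "train_frac must be in (0, 1)")
  .sn_assert(n_components >= 2, "n_components must be >= 2")
  structure(list(n_folds = n_folds, train_frac = train_frac,
                 n_components = n_components, subsample_to = subsample_to,
                 classifier = match.arg(classifier),
                 strict_kfold = strict_kfold, knn_k = knn_k,
                 loess_span = loess_span, seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified cross-validated annotation check
#'
#' Verifies that cell-type labels are recoverable from expression:
#' classes are capped at the median class size, data are split into
#' stratified train/test partitions (default: `n_folds` repeated
#' stratified `train_frac` splits; strict disjoint k-folds by flag), each
#' train partition is reduced to `n_components` by truncated SVD and a
#' classifier is fit; predictions on the held-out cells are aggregated
#' into a confusion matrix. Classes smaller than the fold count are
#' reported as untestable, never silently dropped.
#'
#' @param assay a [count_assay()] with `cell_type`, or a normalized
#'   genes x cells matrix (then `labels` is required).
#' @param cfg a [cv_config()].
#' @param labels optional per-cell labels overriding `cell_type`.
#' @param features optional gene ids to restrict to (marker panel).
#' @return list of class `cv_result`: `confusion` (true x predicted),
#'   `accuracy`, `per_class` (precision/recall/n_test), `untestable`,
#'   `folds` (per-fold test indices).
#' @export
stratified_cv <- function(assay, cfg = cv_config(), labels = NULL,
                          features = NULL) {
  if (inherits(assay, "count_assay")) {
    if (is.null(labels)) labels <- assay$barcode_meta$cell_type
    if (!is.null(features))
      assay <- subset_assay(assay,
                            genes = which(assay$gene_meta$gene_id %in%
                                            features))
    X <- t(loess_normalize(assay, span = cfg$loess_span))
  } else {
    .sn_assert(!is.null(labels), "labels required for matrix input")
    X <- t(as.matrix(assay))
  }
  y <- as.character(labels)
  .sn_assert(nrow(X) == length(y), "one label per cell required")
  set.seed(cfg$seed)

  ## per-class cap at the median class size
  sizes <- table(y)
  if (identical(cfg$subsample_to, "median")) {
    cap <- ceiling(median(sizes))
  } else if (is.numeric(cfg$subsample_to)) {
    cap <- cfg$subsample_to
  } else cap <- Inf
  keep <- unlist(lapply(split(seq_along(y), y), function(ix) {
    if (length(ix) > cap) sample(ix, cap) else ix
  }), use.names = FALSE)
  keep <- sort(keep)
  X <- X[keep, , drop = FALSE]; y <- y[keep]

  sizes <- table(y)
  untestable <- names(sizes)[sizes < cfg$n_folds]
  test_ok <- !(y %in% untestable)
  classes <- sort(unique(y))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  folds <- list()
  split_sets <- .sn_make_splits(y, cfg)
  for (f in seq_along(split_sets)) {
    test_idx <- intersect(split_sets[[f]], which(test_ok))
    train_idx <- setdiff(seq_along(y), split_sets[[f]])
    V <- .sn_truncated_svd(X[train_idx, , drop = FALSE],
                           cfg$n_components)
    tr <- X[train_idx, , drop = FALSE] %*% V
    te <- X[test_idx, , drop = FALSE] %*% V
    pred <- if (cfg$classifier == "multinomial" &&
                requireNamespace("glmnet", quietly = TRUE)) {
      fit <- glmnet::glmnet(tr, factor(y[train_idx]),
                            family = "multinomial", lambda = 1e-3)
      as.character(predict(fit, te, type = "class"))
    } else {
      # cap k at the smallest training class so rare classes are not
      # outvoted by construction
      k_eff <- min(cfg$knn_k, min(table(y[train_idx])))
      .sn_knn_predict(tr, y[train_idx], te, k = k_eff)
    }
    tab <- table(factor(y[test_idx], levels = classes),
                 factor(pred, levels = classes))
    conf <- conf + unclass(tab)
    folds[[f]] <- test_idx
  }
  acc <- sum(diag(conf)) / max(1, sum(conf))
  per_class <- data.frame(
    class = classes,
    n_test = rowSums(conf),
    recall = diag(conf) / pmax(1, rowSums(conf)),
    precision = diag(conf) / pmax(1, colSums(conf)),
    stringsAsFactors = FALSE)
  structure(list(confusion = conf, accuracy = acc,
                 per_class = per_class, untestable = untestable,
                 folds = folds),
            class = "cv_result")
}

## stratified splits: list of test index sets
.sn_make_splits <- function(y, cfg) {
  by_class <- split(seq_along(y), y)
  if (cfg$strict_kfold) {
    assignment <- integer(length(y))
    for (ix in by_class) {
      ix <- sample(ix)
      assignment[ix] <- rep_len(seq_len(cfg$n_folds), length(ix))
    }
    lapply(seq_len(cfg$n_folds), function(f) which(assignment == f))
  } else {
    lapply(seq_len(cfg$n_folds), function(f) {
      unlist(lapply(by_class, function(ix) {
        n_test <- max(1, round((1 - cfg$train_frac) * length(ix)))
        sample(ix, min(n_test, length(ix) - 1))
      }), use.names = FALSE)
    })
  }
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("stratified CV accuracy:", format(x$accuracy, digits = 4), "\n")
  print(x$confusion)
  if (length(x$untestable))
    cat("untestable classes:", paste(x$untestable, collapse = ", "), "\n")
  invisible(x)
}
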