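#' Per-sample cell-type proportion table
#'
#' Tabulates cell counts and within-sample proportions per (sample,
#' cell type), carrying the sample covariates `condition`, `age`, `pmi`.
#' Doublet-flagged barcodes can be excluded first by the caller; counts
#' sum to the number of barcodes supplied.
#'
#' @param assay a [count_assay()] with `cell_type` labels.
#' @return data.frame of class `proportion_table` with columns `sample`,
#'   `cell_type`, `count`, `proportion`, `condition`, `age`, `pmi`.
#' @export
proportion_table <- function(assay) {
  .sn_assert(inherits(assay, "count_assay"), "assay must be a count_assay")
  meta <- assay$barcode_meta
  .sn_assert("cell_type" %in% names(meta), "cell_type labels required")
  tab <- as.data.frame(table(sample = meta$sample,
                             cell_type = meta$cell_type),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tot <- tapply(tab$count, tab$sample, sum)
  tab$proportion <- tab$count / as.numeric(tot[tab$sample])
  samp <- unique(meta[, intersect(c("sample", "condition", "age", "pmi"),
                                  names(meta))])
  tab <- merge(tab, samp, by = "sample", sort = FALSE)
  tab <- tab[order(tab$sample, tab$cell_type), ]
  rownames(tab) <- NULL
  class(tab) <- c("proportion_table", "data.frame")
  tab
}

#' Two-sample t-test on per-sample cell-type proportions
#'
#' The classical (pooled-variance) two-sided Student's t-test on per-sample
#' proportions of one cell type, case versus control; Welch's variant by
#' flag. A tiny variance guard keeps the statistic defined when both
#' groups are constant.
#'
#' @param tbl a [proportion_table()].
#' @param cell_type type to test.
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return list with `t`, `p`, `mean_case`, `mean_control`, `df`, `n`.
#' @export
proportion_test <- function(tbl, cell_type, welch = FALSE) {
  .sn_assert(inherits(tbl, "proportion_table"),
             "tbl must come from proportion_table()")
  sub <- tbl[tbl$cell_type == cell_type, ]
  .sn_assert(nrow(sub) > 0, "unknown cell type: ", cell_type)
  x <- sub$proportion[sub$condition == "case"]
  y <- sub$proportion[sub$condition == "control"]
  .sn_assert(length(x) >= 2 && length(y) >= 2,
             "need at least 2 samples per condition")
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    return(list(t = 0, p = 1, mean_case = mean(x), mean_control = mean(y),
                df = length(x) + length(y) - 2,
                n = c(case = length(x), control = length(y))))
  }
  eps <- 1e-12 * max(abs(c(x, y)), 1)  # variance guard for constant groups
  if (sd(x) == 0 && sd(y) == 0) {
    nx <- length(x); ny <- length(y)
    sp <- eps
    tt <- (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
    df <- nx + ny - 2
    p <- 2 * pt(-abs(tt), df)
    return(list(t = tt, p = p, mean_case = mean(x), mean_control = mean(y),
                df = df, n = c(case = nx, control = ny)))
  }
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_case = mean(x), mean_control = mean(y),
       df = unname(ht$parameter),
       n = c(case = length(x), control = length(y)))
}

## beta log-likelihood with logit mean link and constant precision phi
.sn_betareg_nll <- function(par, y, X) {
  k <- ncol(X)
  eta <- drop(X %*% par[seq_len(k)])
  mu <- 1 / (1 + exp(-eta))
  phi <- exp(par[k + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(stats::dbeta(y, a, b, log = TRUE))
}

#' Maximum-likelihood beta regression of proportions on covariates
#'
#' Models one cell type's per-sample proportion with a beta distribution,
#' logit link for the mean and a constant precision `phi`, estimating the
#' contribution of clinical covariates (condition, age, post-mortem
#' interval) to composition variation. Wald tests per coefficient use the
#' observed-information standard errors. Proportions on the boundary are
#' first shrunk by the usual `(y * (n - 1) + 0.5) / n` adjustment.
#'
#' @param tbl a [proportion_table()].
#' @param cell_type type to model.
#' @param covariates character subset of `c("condition", "age", "pmi")`.
#' @param maxit optimizer iteration cap.
#' @return list of class `betareg_fit`: `coefficients` (data.frame with
#'   estimate, se, z, p per term), `phi`, `converged`, `fitted`, `n`.
#' @export
fit_beta_regression <- function(tbl, cell_type,
                                covariates = c("condition", "age", "pmi"),
                                maxit = 500) {
  .sn_assert(inherits(tbl, "proportion_table"),
             "tbl must come from proportion_table()")
  sub <- tbl[tbl$cell_type == cell_type, , drop = FALSE]
  .sn_assert(nrow(sub) > 0, "unknown cell type: ", cell_type)
  covariates <- intersect(covariates, names(sub))
  y <- sub$proportion
  n <- length(y)
  .sn_assert(n >= length(covariates) + 2,
             "need at least p + 2 samples to fit")
  if (any(y <= 0 | y >= 1)) y <- (y * (n - 1) + 0.5) / n
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  for (cv in covariates) {
    col <- if (cv == "condition") as.numeric(sub$condition == "case")
           else as.numeric(sub[[cv]])
    X <- cbind(X, setNames(data.frame(col), cv))
  }
  X <- as.matrix(X)
  # starting values from OLS on the empirical logit
  z0 <- log(y / (1 - y))
  b0 <- tryCatch(qr.solve(X, z0), error = function(e) rep(0, ncol(X)))
  start <- c(b0, log_phi = log(10))
  fit <- optim(start, .sn_betareg_nll, y = y, X = X, method = "BFGS",
               control = list(maxit = maxit), hessian = TRUE)
  k <- ncol(X)
  se <- rep(NA_real_, k + 1)
  ok <- fit$convergence == 0
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc) && all(diag(vc)[seq_len(k)] > 0))
    se <- sqrt(pmax(diag(vc), 0))
  else ok <- FALSE
  est <- fit$par[seq_len(k)]
  zstat <- est / se[seq_len(k)]
  coefs <- data.frame(term = colnames(X), estimate = unname(est),
                      se = se[seq_len(k)], z = unname(zstat),
                      p = 2 * pnorm(-abs(unname(zstat))),
                      stringsAsFactors = FALSE)
  mu <- 1 / (1 + exp(-drop(X %*% est)))
  structure(list(coefficients = coefs, phi = exp(fit$par[k + 1]),
                 converged = ok, fitted = mu, n = n,
                 cell_type = cell_type),
            class = "betareg_fit")
}

#' @exportS3Method base::print
print.betareg_fit <- function(x, ...) {
  cat("beta regression for", x$cell_type,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$coefficients, digits = 4)
  cat("phi =", format(x$phi, digits = 4), " n =", x$n, "\n")
  invisible(x)
}
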