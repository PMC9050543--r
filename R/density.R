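#' 2D embedding kernel density for one condition
#'
#' Gaussian-kernel 2D density of one condition's cells on a shared
#' `bins x bins` grid spanning the union range of both conditions (so the
#' case and control grids are directly comparable), with normal-reference
#' bandwidths per axis. The grid values are renormalized to integrate to 1.
#'
#' @param cells a [count_assay()] with `umap_1`/`umap_2` and `condition`
#'   in `barcode_meta`, or a data.frame with those columns.
#' @param condition `"case"` or `"control"`: the condition whose cells are
#'   used.
#' @param bins grid resolution per axis (default 100).
#' @param lims optional `c(xmin, xmax, ymin, ymax)`; defaults to the union
#'   range over all cells (both conditions), expanded by 5%.
#' @param bandwidth optional length-2 kernel bandwidth (x, y); default is
#'   the normal-reference rule per axis (which scales with `n^(-1/5)`).
#' @return list of class `embedding_density` with `x`, `y` (bin centres),
#'   `z` (density matrix), `n`, `condition`.
#' @export
embedding_density <- function(cells, condition, bins = 100, lims = NULL,
                              bandwidth = NULL) {
  meta <- if (inherits(cells, "count_assay")) cells$barcode_meta else cells
  .sn_assert(all(c("umap_1", "umap_2", "condition") %in% names(meta)),
             "need umap_1, umap_2 and condition columns")
  sel <- meta$condition == condition
  .sn_assert(sum(sel) >= 10, "need at least 10 cells for condition '",
             condition, "'")
  x <- meta$umap_1[sel]; y <- meta$umap_2[sel]
  .sn_assert(sd(x) > 0, "degenerate (zero-variance) axis: umap_1")
  .sn_assert(sd(y) > 0, "degenerate (zero-variance) axis: umap_2")
  if (is.null(lims)) {
    rx <- range(meta$umap_1); ry <- range(meta$umap_2)
    ex <- diff(rx) * 0.05; ey <- diff(ry) * 0.05
    lims <- c(rx[1] - ex, rx[2] + ex, ry[1] - ey, ry[2] + ey)
  }
  kd <- if (is.null(bandwidth)) MASS::kde2d(x, y, n = bins, lims = lims)
        else MASS::kde2d(x, y, h = bandwidth, n = bins, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  kd$z <- kd$z / (sum(kd$z) * dx * dy)
  structure(list(x = kd$x, y = kd$y, z = kd$z, n = sum(sel),
                 condition = condition),
            class = "embedding_density")
}

#' Log2 differential density between case and control grids
#'
#' `log2((case + floor) / (control + floor))` per grid cell; cells where
#' both densities fall below the floor are masked (`NA`). The default
#' floor is one count spread over the whole grid area:
#' `1 / (n_total * grid_area)`.
#'
#' @param case_d,control_d [embedding_density()] objects on the same grid.
#' @param floor density floor; `NULL` for the default.
#' @return list of class `density_grid` with `x`, `y`, `log2_ratio`
#'   (matrix, `NA` where masked), `floor`, plus the two input densities.
#' @export
differential_density <- function(case_d, control_d, floor = NULL) {
  .sn_assert(inherits(case_d, "embedding_density") &&
               inherits(control_d, "embedding_density"),
             "inputs must come from embedding_density()")
  .sn_assert(isTRUE(all.equal(case_d$x, control_d$x)) &&
               isTRUE(all.equal(case_d$y, control_d$y)),
             "density grids do not match")
  if (is.null(floor)) {
    area <- diff(range(case_d$x)) * diff(range(case_d$y))
    floor <- 1 / ((case_d$n + control_d$n) * area)
  }
  lr <- log2((case_d$z + floor) / (control_d$z + floor))
  lr[case_d$z < floor & control_d$z < floor] <- NA_real_
  structure(list(x = case_d$x, y = case_d$y, log2_ratio = lr,
                 floor = floor, density_case = case_d$z,
                 density_control = control_d$z),
            class = "density_grid")
}

#' Differential density of a case/control embedding in one call
#'
#' @param cells as in [embedding_density()].
#' @param bins grid resolution.
#' @param floor see [differential_density()].
#' @return a `density_grid`.
#' @export
condition_density_contrast <- function(cells, bins = 100, floor = NULL) {
  dc <- embedding_density(cells, "case", bins = bins)
  d0 <- embedding_density(cells, "control", bins = bins)
  differential_density(dc, d0, floor = floor)
}
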