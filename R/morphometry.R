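#' Segmentation parameters
#'
#' @param gaussian_sigma pre-smoothing SD in pixels (0 = none).
#' @param threshold pixel threshold; interpreted per `threshold_mode`.
#' @param threshold_mode `"absolute"` intensity or `"quantile"` of the
#'   channel's intensity distribution (in `[0, 1]`).
#' @param min_object_px connected components smaller than this are
#'   removed.
#' @param fill_holes fill enclosed background after thresholding.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(gaussian_sigma = 0, threshold,
                                threshold_mode = c("absolute", "quantile"),
                                min_object_px = 0, fill_holes = FALSE) {
  .sn_assert(gaussian_sigma >= 0, "gaussian_sigma must be >= 0")
  .sn_assert(min_object_px >= 0, "min_object_px must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma, threshold = threshold,
                 threshold_mode = match.arg(threshold_mode),
                 min_object_px = min_object_px, fill_holes = fill_holes),
            class = "segmentation_params")
}

.sn_resolve_threshold <- function(channel, p) {
  if (p$threshold_mode == "quantile")
    quantile(channel, p$threshold, names = FALSE)
  else p$threshold
}

#' Segment bright objects in a channel
#'
#' Gaussian smooth (if `gaussian_sigma > 0`), binarize at `>= threshold`,
#' remove components below `min_object_px`, optionally fill holes, and
#' label 8-connected objects.
#'
#' @param channel 2D intensity matrix.
#' @param p a [segmentation_params()].
#' @return integer label matrix.
#' @export
segment_bright <- function(channel, p) {
  .sn_assert(is.matrix(channel), "channel must be a 2D matrix")
  img <- gaussian_blur(channel, p$gaussian_sigma)
  thr <- .sn_resolve_threshold(img, p)
  if (thr > max(img)) {
    warning("threshold above the intensity range; empty mask")
    return(matrix(0L, nrow(channel), ncol(channel)))
  }
  bin <- img >= thr
  lab <- remove_small(label_components(bin), p$min_object_px)
  if (p$fill_holes) lab <- label_components(fill_holes(lab > 0))
  lab
}

#' Segment dark objects (e.g. neuromelanin deposits)
#'
#' Binarize at `<= threshold` then proceed as [segment_bright()].
#' Running [segment_bright()] on the inverted image with the mirrored
#' threshold yields the identical mask.
#'
#' @param channel 2D intensity matrix.
#' @param p a [segmentation_params()] (quantile mode takes the lower
#'   quantile).
#' @return integer label matrix.
#' @export
segment_dark <- function(channel, p) {
  .sn_assert(is.matrix(channel), "channel must be a 2D matrix")
  img <- gaussian_blur(channel, p$gaussian_sigma)
  thr <- .sn_resolve_threshold(img, p)
  if (thr < min(img)) {
    warning("threshold below the intensity range; empty mask")
    return(matrix(0L, nrow(channel), ncol(channel)))
  }
  bin <- img <= thr
  lab <- remove_small(label_components(bin), p$min_object_px)
  if (p$fill_holes) lab <- label_components(fill_holes(lab > 0))
  lab
}

#' Positive-area fraction per region
#'
#' Thresholds the channel (bright rule) and reports the positive-pixel
#' fraction per region of the label mask and for the whole image. Empty
#' regions give `NA` with a flag.
#'
#' @param channel 2D intensity matrix.
#' @param p a [segmentation_params()].
#' @param region_mask integer label matrix with a `levels` attribute, or
#'   `NULL` for whole-image only.
#' @return data.frame `region`, `fraction`, `n_px`, `flagged`.
#' @export
area_fraction <- function(channel, p, region_mask = NULL) {
  img <- gaussian_blur(channel, p$gaussian_sigma)
  thr <- .sn_resolve_threshold(img, p)
  pos <- img >= thr
  out <- data.frame(region = "all", fraction = mean(pos),
                    n_px = length(pos), flagged = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(region_mask)) {
    .sn_assert(all(dim(region_mask) == dim(channel)),
               "region mask not aligned with channel")
    levs <- attr(region_mask, "levels")
    if (is.null(levs)) levs <- as.character(sort(unique(
      region_mask[region_mask > 0])))
    for (k in seq_along(levs)) {
      sel <- region_mask == k
      n <- sum(sel)
      out <- rbind(out, data.frame(
        region = levs[k],
        fraction = if (n == 0) NA_real_ else mean(pos[sel]),
        n_px = n, flagged = n == 0, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Skeleton branching statistics per object
#'
#' Thins every labeled object to a 1-px skeleton, prunes spurs shorter
#' than `min_spur`, and counts branch points and endpoints. A branch
#' point is a skeleton pixel whose crossing number (distinct 0-to-1
#' transitions in the circular 8-neighbour sequence, i.e. distinct
#' skeletal branches leaving the pixel) is >= 3; an endpoint has crossing
#' number 1. The raw ">= 3 neighbours" count is reported as
#' `neighbor3_px` for reference, but it over-flags pixels diagonally
#' adjacent to a junction even on a perfect cross skeleton, so the
#' crossing-number rule is the documented branching statistic.
#' `branching_index` is the branch-point count per object;
#' `branch_per_100px` normalizes by skeleton length.
#'
#' @param mask integer label matrix (or logical, labeled first).
#' @param min_spur spur-suppression length (default 3 px).
#' @return data.frame `object`, `skeleton_px`, `branch_points`,
#'   `endpoints`, `branching_index`, `branch_per_100px`, `neighbor3_px`.
#' @export
skeleton_branching <- function(mask, min_spur = 3) {
  if (is.logical(mask)) mask <- label_components(mask)
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  if (length(ids) == 0)
    return(data.frame(object = integer(0), skeleton_px = integer(0),
                      branch_points = integer(0), endpoints = integer(0),
                      branching_index = integer(0),
                      branch_per_100px = numeric(0),
                      neighbor3_px = integer(0)))
  out <- lapply(ids, function(id) {
    sel <- which(mask == id, arr.ind = TRUE)
    # crop with 1-px margin to keep thinning cheap
    yr <- max(1, min(sel[, 1]) - 1):min(nrow(mask), max(sel[, 1]) + 1)
    xr <- max(1, min(sel[, 2]) - 1):min(ncol(mask), max(sel[, 2]) + 1)
    sub <- mask[yr, xr, drop = FALSE] == id
    sk <- prune_spurs(thin_skeleton(sub), min_spur)
    cn <- .sn_crossing_number(sk)
    nc <- .sn_neighbor_count(sk)
    bp <- sum(sk & cn >= 3)
    ep <- sum(sk & cn == 1)
    npx <- sum(sk)
    data.frame(object = id, skeleton_px = npx, branch_points = bp,
               endpoints = ep, branching_index = bp,
               branch_per_100px = if (npx > 0) 100 * bp / npx else 0,
               neighbor3_px = sum(sk & nc >= 3))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-individual, per-region morphometry summary
#'
#' Arithmetic means of object-level metrics per individual (and region
#' when present). Individuals contributing zero objects are dropped with
#' a notice.
#'
#' @param records data.frame of object- or image-level records with
#'   columns `individual`, `condition`, optionally `region`, and the
#'   metric columns.
#' @param metrics metric column names to average.
#' @return data.frame `individual`, `condition`, `region`, one mean
#'   column per metric, `n`.
#' @export
per_individual_summary <- function(records,
                                   metrics = intersect(
                                     c("area_px", "branching_index",
                                       "fraction"), names(records))) {
  .sn_assert(all(c("individual", "condition") %in% names(records)),
             "records need 'individual' and 'condition' columns")
  .sn_assert(length(metrics) > 0, "no metric columns found")
  if (!"region" %in% names(records)) records$region <- "all"
  recs <- rbind(records,
                within(records, region <- "all")[records$region != "all", ])
  agg <- aggregate(recs[metrics],
                   by = recs[c("individual", "condition", "region")],
                   FUN = mean, na.rm = TRUE)
  cnt <- aggregate(list(n = recs[[metrics[1]]]),
                   by = recs[c("individual", "condition", "region")],
                   FUN = length)
  merge(agg, cnt, by = c("individual", "condition", "region"),
        sort = TRUE)
}

#' Unpaired group comparison of per-individual summaries
#'
#' Two-sided unpaired t-test of one metric between case and control
#' individuals, per region.
#'
#' @param summaries output of [per_individual_summary()].
#' @param metric metric column to compare.
#' @param region region to use (default `"all"`, the whole image).
#' @param welch Welch's variant instead of pooled variance.
#' @return list `t`, `p`, `mean_case`, `mean_control`, `n`.
#' @export
group_compare <- function(summaries, metric, region = "all",
                          welch = FALSE) {
  .sn_assert(metric %in% names(summaries), "unknown metric: ", metric)
  sub <- summaries[summaries$region == region, ]
  x <- sub[[metric]][sub$condition == "case"]
  y <- sub[[metric]][sub$condition == "control"]
  .sn_assert(length(x) >= 2 && length(y) >= 2,
             "need at least 2 individuals per group")
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value, mean_case = mean(x),
       mean_control = mean(y),
       n = c(case = length(x), control = length(y)))
}
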