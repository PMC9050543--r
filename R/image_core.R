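## Low-level 2D image operations (matrices indexed [row = y, col = x]).
## No imaging package in the dependency stack provides these, so they are
## implemented here; all are exercised against brute-force oracles in the
## test suite.

#' Separable Gaussian blur
#'
#' @param img numeric matrix.
#' @param sigma kernel SD in pixels; 0 returns the input unchanged.
#' @return blurred matrix of the same shape (replicate-padded borders).
#' @export
gaussian_blur <- function(img, sigma) {
  .sn_assert(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {  # along rows (vertical), replicate padding
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(nr) + j, 1L), nr)
      out <- out + k[j + r + 1] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

.sn_shifts8 <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                    c(1, -1), c(1, 0), c(1, 1))

## shift a matrix by (dy, dx), filling with `fill`
.sn_shift <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

#' Connected-component labeling
#'
#' Labels foreground pixels by iterative minimum-label propagation.
#'
#' @param bin logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 = background, objects numbered 1..K in
#'   raster order of their smallest pixel index.
#' @export
label_components <- function(bin, connectivity = 8) {
  .sn_assert(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  sh <- if (connectivity == 8) .sn_shifts8 else
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  lab <- matrix(0, nrow(bin), ncol(bin))
  lab[bin] <- seq_len(sum(bin))
  full <- matrix(seq_along(bin), nrow(bin))  # unique init per pixel
  lab[bin] <- full[bin]
  repeat {
    new <- lab
    for (s in sh) {
      nb <- .sn_shift(lab, s[1], s[2], fill = 0)
      upd <- bin & nb > 0 & (new == 0 | nb < new)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(bin), ncol(bin))
  out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Remove small connected components
#'
#' @param lab label matrix from [label_components()] (or logical matrix,
#'   which is labeled first).
#' @param min_px components with fewer pixels are dropped.
#' @return relabeled integer matrix.
#' @export
remove_small <- function(lab, min_px) {
  if (is.logical(lab)) lab <- label_components(lab)
  if (min_px <= 1) return(lab)
  sz <- tabulate(lab[lab > 0])
  keep <- which(sz >= min_px)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0 & lab %in% keep
  out[sel] <- match(lab[sel], keep)
  out
}

#' Fill holes in a binary mask
#'
#' A hole is a background component (4-connected) not touching the image
#' border.
#'
#' @param bin logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(bin) {
  bg <- label_components(!bin, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- setdiff(border, 0L)
  bin | (bg > 0 & !(bg %in% border))
}

## 8-neighbour count of TRUE pixels, per pixel
.sn_neighbor_count <- function(bin) {
  b <- bin * 1
  out <- matrix(0, nrow(bin), ncol(bin))
  for (s in .sn_shifts8) out <- out + .sn_shift(b, s[1], s[2], 0)
  out
}

## crossing number: 0->1 transitions in the circular 8-neighbour sequence.
## Counts the distinct skeletal branches leaving each pixel: 1 = endpoint,
## 2 = path interior, >= 3 = junction. The raw neighbour count over-flags
## pixels diagonally adjacent to a junction even on a perfect skeleton.
.sn_crossing_number <- function(bin) {
  b <- bin * 1L
  p2 <- .sn_shift(b, 1, 0);  p3 <- .sn_shift(b, 1, -1)
  p4 <- .sn_shift(b, 0, -1); p5 <- .sn_shift(b, -1, -1)
  p6 <- .sn_shift(b, -1, 0); p7 <- .sn_shift(b, -1, 1)
  p8 <- .sn_shift(b, 0, 1);  p9 <- .sn_shift(b, 1, 1)
  seqp <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  cn <- matrix(0L, nrow(bin), ncol(bin))
  for (i in 1:8) cn <- cn + (seqp[[i]] == 0 & seqp[[i + 1]] == 1)
  cn
}

#' Morphological thinning (Guo-Hall)
#'
#' Reduces a binary object to a 1-pixel-wide 8-connected skeleton using
#' the two-subiteration Guo-Hall scheme, which preserves diagonal
#' structures that simpler thinning rules erode.
#'
#' @param bin logical matrix.
#' @return logical skeleton matrix.
#' @export
thin_skeleton <- function(bin) {
  img <- bin * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # clockwise neighbours P2..P9 starting north
      p2 <- .sn_shift(img, 1, 0);  p3 <- .sn_shift(img, 1, -1)
      p4 <- .sn_shift(img, 0, -1); p5 <- .sn_shift(img, -1, -1)
      p6 <- .sn_shift(img, -1, 0); p7 <- .sn_shift(img, -1, 1)
      p8 <- .sn_shift(img, 0, 1);  p9 <- .sn_shift(img, 1, 1)
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      m <- if (step == 1) ((p6 | p7 | !p9) & p8) else
        ((p2 | p3 | !p5) & p4)
      del <- img == 1 & C == 1 & N >= 2 & N <= 3 & m == 0
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1
}

#' Prune short skeleton spurs
#'
#' Walks from each skeleton endpoint; if a junction (pixel with >= 3
#' skeleton neighbours) is reached in fewer than `min_spur` steps, the
#' walked pixels are removed. Thinning artifacts otherwise inflate branch
#' counts.
#'
#' @param skel logical skeleton matrix.
#' @param min_spur minimum branch length in pixels to survive (default 3).
#' @return pruned logical matrix.
#' @export
prune_spurs <- function(skel, min_spur = 3) {
  if (min_spur <= 1) return(skel)
  repeat {
    cn <- .sn_crossing_number(skel)
    ends <- which(skel & cn == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) break
    removed_any <- FALSE
    for (ei in seq_len(nrow(ends))) {
      start <- unname(ends[ei, ])
      if (!skel[start[1], start[2]]) next   # consumed by earlier pruning
      path <- list(start)
      cur <- start
      prev <- NULL
      hit_junction <- FALSE
      while (length(path) < min_spur) {
        nbs <- .sn_skel_neighbors(skel, cur)
        if (!is.null(prev))
          nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), ,
                     drop = FALSE]
        if (nrow(nbs) == 0) break           # isolated short segment
        if (nrow(nbs) > 1) { hit_junction <- TRUE; break }
        nxt <- unname(nbs[1, ])
        if (cn[nxt[1], nxt[2]] >= 3) {
          hit_junction <- TRUE
          break
        }
        prev <- cur; cur <- nxt
        path[[length(path) + 1]] <- cur
      }
      if (hit_junction && length(path) < min_spur) {
        for (p in path) skel[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

.sn_skel_neighbors <- function(skel, p) {
  out <- NULL
  for (s in .sn_shifts8) {
    y <- p[1] + s[1]; x <- p[2] + s[2]
    if (y >= 1 && y <= nrow(skel) && x >= 1 && x <= ncol(skel) &&
        skel[y, x])
      out <- rbind(out, c(y, x))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

.sn_neighbor_count_at <- function(skel, p) {
  nrow(.sn_skel_neighbors(skel, p))
}
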