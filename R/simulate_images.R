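#' Configuration for the immunofluorescence image simulator
#'
#' Generates per-marker 2D fluorescence canvases with pixel-aligned
#' ground-truth label masks. Marker conventions: TH (dopaminergic somata)
#' and GFAP render as bright discs/branched cells, IBA1 (microglia) as a
#' capsule-shaped soma with `branch_count` processes attached at distinct
#' points (so the skeleton junction count has exact ground truth), NM
#' (neuromelanin) as dark deposits on a bright field, PLP1 (myelin) as
#' diffuse bright patches.
#'
#' @param width,height canvas size in pixels.
#' @param channels character subset of TH, NM, GFAP, IBA1, PLP1.
#' @param n_cells_per_channel objects rendered per channel.
#' @param branch_count integer (recycled per cell): processes per
#'   IBA1/GFAP cell.
#' @param soma_radius,process_length morphology parameters in pixels
#'   (recycled per cell).
#' @param background_level,foreground_level,noise_sd intensity units; for
#'   NM the foreground must be darker than the background.
#' @param region_layout `"quadrants"` (SN, NR, TT, CC) or `"none"`.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @return a `sim_image_config` list.
#' @export
sim_image_config <- function(width = 256, height = 256,
                             channels = c("TH", "NM", "GFAP", "IBA1",
                                          "PLP1"),
                             n_cells_per_channel = 8,
                             branch_count = 4,
                             soma_radius = 6,
                             process_length = 18,
                             background_level = 2000,
                             foreground_level = 12000,
                             noise_sd = 300,
                             region_layout = c("quadrants", "none"),
                             pixel_size = 0.65,
                             seed = 1L) {
  .sn_assert(length(channels) > 0, "zero channels requested")
  known <- c("TH", "NM", "GFAP", "IBA1", "PLP1")
  .sn_assert(all(channels %in% known),
             "channels must be a subset of ", paste(known, collapse = ", "))
  .sn_assert(foreground_level > background_level,
             "foreground_level must exceed background_level for bright ",
             "channels (NM is rendered dark automatically)")
  .sn_assert(all(branch_count >= 0), "branch_count must be >= 0")
  structure(list(width = width, height = height, channels = channels,
                 n_cells_per_channel = n_cells_per_channel,
                 branch_count = branch_count, soma_radius = soma_radius,
                 process_length = process_length,
                 background_level = background_level,
                 foreground_level = foreground_level, noise_sd = noise_sd,
                 region_layout = match.arg(region_layout),
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "sim_image_config")
}

## pixels within `hw` of the segment (x1,y1)-(x2,y2); returns logical
.sn_capsule <- function(h, w, x1, y1, x2, y2, hw) {
  xr <- max(1, floor(min(x1, x2) - hw - 1)):min(w, ceiling(max(x1, x2) +
                                                             hw + 1))
  yr <- max(1, floor(min(y1, y2) - hw - 1)):min(h, ceiling(max(y1, y2) +
                                                             hw + 1))
  out <- matrix(FALSE, h, w)
  if (length(xr) == 0 || length(yr) == 0) return(out)
  gx <- matrix(xr, length(yr), length(xr), byrow = TRUE)
  gy <- matrix(yr, length(yr), length(xr))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else
    pmin(pmax(((gx - x1) * dx + (gy - y1) * dy) / len2, 0), 1)
  d2 <- (gx - (x1 + t * dx))^2 + (gy - (y1 + t * dy))^2
  out[yr, xr] <- d2 <= hw^2
  out
}

.sn_disc <- function(h, w, cx, cy, r) .sn_capsule(h, w, cx, cy, cx, cy, r)

## one branched cell: capsule soma + perpendicular processes attached at
## distinct anchors along the soma axis, alternating sides.
.sn_render_branched <- function(h, w, cx, cy, angle, soma_radius,
                                branch_count, process_length) {
  half <- soma_radius * 2
  ux <- cos(angle); uy <- sin(angle)
  px <- -uy; py <- ux
  shape <- .sn_capsule(h, w, cx - half * ux, cy - half * uy,
                       cx + half * ux, cy + half * uy, soma_radius / 2)
  if (branch_count > 0) {
    anchors <- seq(-0.75, 0.75, length.out = branch_count) * half
    for (b in seq_len(branch_count)) {
      side <- if (b %% 2 == 0) 1 else -1
      ax <- cx + anchors[b] * ux; ay <- cy + anchors[b] * uy
      shape <- shape | .sn_capsule(h, w, ax, ay,
                                   ax + side * process_length * px,
                                   ay + side * process_length * py, 1.2)
    }
  }
  shape
}

#' Simulate a multi-channel fluorescence image with truth masks
#'
#' @param cfg a [sim_image_config()].
#' @return object of class `channel_stack`: `channels` (named intensity
#'   matrices), `masks` (named integer label matrices, pixel-aligned with
#'   the channels), `region_mask` (integer matrix, levels in
#'   `attr(,"levels")`), `pixel_size`; the per-object truth table (id,
#'   channel, centre, area_px, branch_count, region) in
#'   `attr(x, "truth")$objects`.
#' @export
simulate_images <- function(cfg) {
  .sn_assert(inherits(cfg, "sim_image_config"),
             "cfg must come from sim_image_config()")
  set.seed(cfg$seed)
  h <- cfg$height; w <- cfg$width
  region_mask <- NULL
  region_levels <- c("SN", "NR", "TT", "CC")
  if (cfg$region_layout == "quadrants") {
    region_mask <- matrix(0L, h, w)
    region_mask[seq_len(floor(h / 2)), seq_len(floor(w / 2))] <- 1L
    region_mask[seq_len(floor(h / 2)), (floor(w / 2) + 1):w] <- 2L
    region_mask[(floor(h / 2) + 1):h, seq_len(floor(w / 2))] <- 3L
    region_mask[(floor(h / 2) + 1):h, (floor(w / 2) + 1):w] <- 4L
    attr(region_mask, "levels") <- region_levels
  }
  channels <- masks <- list()
  objects <- NULL
  overlaps <- 0L
  margin <- cfg$soma_radius + cfg$process_length + 2
  for (ch in cfg$channels) {
    canvas <- matrix(cfg$background_level, h, w)
    lab <- matrix(0L, h, w)
    n <- cfg$n_cells_per_channel
    bc <- rep_len(cfg$branch_count, n)
    sr <- rep_len(cfg$soma_radius, n)
    pl <- rep_len(cfg$process_length, n)
    placed <- NULL
    for (i in seq_len(n)) {
      # best-effort non-overlapping placement by rejection sampling
      ok <- FALSE
      for (try in 1:50) {
        cx <- runif(1, margin, w - margin)
        cy <- runif(1, margin, h - margin)
        if (is.null(placed) ||
            all((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 >
                  (2.2 * margin)^2 / 4)) { ok <- TRUE; break }
      }
      if (!ok) overlaps <- overlaps + 1L
      placed <- rbind(placed, c(cx, cy))
      shape <- switch(ch,
        IBA1 = , GFAP = .sn_render_branched(h, w, cx, cy,
                                            runif(1, 0, pi), sr[i],
                                            bc[i], pl[i]),
        TH = .sn_disc(h, w, cx, cy, sr[i]),
        NM = .sn_disc(h, w, cx, cy, sr[i]),
        PLP1 = {
          patch <- .sn_disc(h, w, cx, cy, sr[i] * 1.6)
          for (s in 1:2)
            patch <- patch | .sn_disc(h, w, cx + rnorm(1, 0, sr[i]),
                                      cy + rnorm(1, 0, sr[i]),
                                      sr[i] * 1.2)
          patch
        })
      if (any(lab[shape] > 0)) overlaps <- overlaps + 1L
      lab[shape] <- i
      canvas[shape] <- if (ch == "NM")
        max(0, 2 * cfg$background_level - cfg$foreground_level)
      else cfg$foreground_level
      cyi <- min(max(round(cy), 1), h); cxi <- min(max(round(cx), 1), w)
      objects <- rbind(objects, data.frame(
        channel = ch, object = i, cx = cx, cy = cy,
        area_px = sum(lab == i), branch_count = bc[i],
        region = if (is.null(region_mask)) NA_character_ else
          region_levels[region_mask[cyi, cxi]],
        stringsAsFactors = FALSE))
    }
    # areas after all placements (later objects may overwrite earlier)
    sel <- objects$channel == ch
    objects$area_px[sel] <- tabulate(lab, nbins = n)[objects$object[sel]]
    canvas <- canvas + matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
    channels[[ch]] <- pmax(canvas, 0)
    masks[[ch]] <- lab
  }
  if (overlaps > 0)
    message(overlaps, " object placement overlap(s) logged")
  out <- structure(list(channels = channels, masks = masks,
                        region_mask = region_mask,
                        pixel_size = cfg$pixel_size),
                   class = "channel_stack")
  attr(out, "truth") <- list(objects = objects, overlaps = overlaps,
                             config = unclass(cfg))
  out
}

#' Simulate a two-group IBA1 morphology cohort
#'
#' Controls carry ramified microglia (many processes); cases carry
#' amoeboid microglia (few processes, larger somata, more cells) --
#' the planted direction of disease-associated microglial activation.
#'
#' @param n_control,n_case individuals per group.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_image_config()].
#' @return list with `stacks` (one `channel_stack` per individual) and
#'   `individuals` (data.frame `individual`, `condition`).
#' @export
simulate_iba1_cohort <- function(n_control = 5, n_case = 6, seed = 1L,
                                 ...) {
  inds <- data.frame(
    individual = sprintf("I%02d", seq_len(n_control + n_case)),
    condition = rep(c("control", "case"), c(n_control, n_case)),
    stringsAsFactors = FALSE)
  stacks <- lapply(seq_len(nrow(inds)), function(i) {
    amoeboid <- inds$condition[i] == "case"
    cfg <- sim_image_config(
      channels = "IBA1",
      n_cells_per_channel = if (amoeboid) 10 else 7,
      branch_count = if (amoeboid) c(0, 1) else c(5, 6),
      soma_radius = if (amoeboid) 9 else 6,
      process_length = if (amoeboid) 8 else 20,
      seed = seed * 1000L + i, ...)
    simulate_images(cfg)
  })
  names(stacks) <- inds$individual
  list(stacks = stacks, individuals = inds)
}
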