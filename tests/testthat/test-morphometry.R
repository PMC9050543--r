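test_that("gaussian blur preserves mass away from borders and matches a
           brute-force kernel sum", {
  set.seed(71)
  img <- matrix(runif(400, 0, 10), 20, 20)
  bl <- gaussian_blur(img, sigma = 1)
  expect_equal(dim(bl), dim(img))
  # brute-force 2D kernel at an interior pixel
  r <- 3
  k1 <- dnorm(-r:r, sd = 1); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  manual <- sum(img[10 + (-r:r), 10 + (-r:r)] * k2)
  expect_equal(bl[10, 10], manual, tolerance = 1e-12)
  expect_identical(gaussian_blur(img, 0), img)
})

test_that("connected-component labeling follows 8-connectivity semantics", {
  bin <- matrix(FALSE, 10, 10)
  bin[2:3, 2:3] <- TRUE           # object 1
  bin[5, 5] <- TRUE               # touches object 1? no (gap)
  bin[4, 4] <- TRUE               # diagonal bridge 3,3 -> 4,4 -> 5,5
  lab <- label_components(bin)
  expect_equal(max(lab), 1L)      # all diagonal-connected
  lab4 <- label_components(bin, connectivity = 4)
  expect_equal(max(lab4), 3L)     # 4-connectivity splits them
  # two discs separated by > 1 px stay distinct; touching discs merge
  two <- disc_mask(40, 40, 10, 20, 5) | disc_mask(40, 40, 28, 20, 5)
  expect_equal(max(label_components(two)), 2L)
  touching <- disc_mask(40, 40, 10, 20, 5) | disc_mask(40, 40, 19, 20, 5)
  expect_equal(max(label_components(touching)), 1L)
})

test_that("mask area conservation: per-object areas sum to positive
           pixels", {
  set.seed(72)
  bin <- matrix(runif(2500) < 0.3, 50, 50)
  lab <- label_components(bin)
  expect_equal(sum(tabulate(lab[lab > 0])), sum(bin))
})

test_that("fill_holes fills enclosed background only", {
  ring <- disc_mask(30, 30, 15, 15, 10) & !disc_mask(30, 30, 15, 15, 5)
  filled <- fill_holes(ring)
  expect_equal(sum(filled), sum(disc_mask(30, 30, 15, 15, 10)))
  bar <- matrix(FALSE, 10, 10); bar[5, 2:9] <- TRUE
  expect_identical(fill_holes(bar), bar)
})

test_that("segment_bright recovers a synthetic disc area within 2%", {
  st <- simulate_images(sim_image_config(
    channels = "TH", n_cells_per_channel = 1, soma_radius = 10,
    noise_sd = 100, seed = 73))
  p <- segmentation_params(gaussian_sigma = 0, threshold = 7000,
                           min_object_px = 10)
  lab <- segment_bright(st$channels$TH, p)
  expect_equal(max(lab), 1L)
  truth <- attr(st, "truth")$objects$area_px
  expect_lt(abs(sum(lab > 0) - truth) / truth, 0.02)
  # threshold above intensity range
  p2 <- segmentation_params(threshold = 1e6)
  expect_warning(empty <- segment_bright(st$channels$TH, p2), "range")
  expect_equal(max(empty), 0L)
})

test_that("segmentation is idempotent on its own binary output", {
  st <- simulate_images(sim_image_config(
    channels = "TH", n_cells_per_channel = 3, seed = 74))
  p <- segmentation_params(threshold = 7000, min_object_px = 10)
  lab <- segment_bright(st$channels$TH, p)
  again <- segment_bright((lab > 0) * 1, segmentation_params(
    threshold = 0.5, min_object_px = 0))
  expect_identical(again > 0, lab > 0)
})

test_that("segment_dark recovers dark blobs and equals inverted
           segment_bright (duality)", {
  st <- simulate_images(sim_image_config(
    channels = "NM", n_cells_per_channel = 4, soma_radius = 7,
    noise_sd = 100, seed = 75))
  img <- st$channels$NM
  p <- segmentation_params(threshold = 1000, min_object_px = 10)
  dark <- segment_dark(img, p)
  truth <- attr(st, "truth")$objects
  expect_equal(max(dark), nrow(truth))
  areas <- tabulate(dark)
  expect_lt(max(abs(sort(areas) - sort(truth$area_px)) /
                  sort(truth$area_px)), 0.05)
  # duality: bright segmentation of the inverted image, mirrored threshold
  inv <- max(img) - img
  bright <- segment_bright(inv, segmentation_params(
    threshold = max(img) - 1000, min_object_px = 10))
  expect_identical(bright > 0, dark > 0)
  # uniformly bright image -> empty
  expect_warning(e <- segment_dark(matrix(5000, 20, 20), p), "range")
  expect_equal(max(e), 0L)
})

test_that("area_fraction: exact fractions, quantile invariance, empty
           region flag", {
  img <- matrix(0, 40, 40)
  img[1:20, 1:20][seq_len(200)] <- 100   # half of region 1 positive
  region <- matrix(0L, 40, 40)
  region[1:20, 1:20] <- 1L
  region[1:20, 21:40] <- 2L
  attr(region, "levels") <- c("SN", "NR")
  p <- segmentation_params(threshold = 50)
  fr <- area_fraction(img, p, region)
  expect_equal(fr$fraction[fr$region == "SN"], 0.5)
  expect_equal(fr$fraction[fr$region == "NR"], 0)
  # quantile mode is invariant to intensity rescaling
  set.seed(76)
  img2 <- matrix(rgamma(1600, 2, 1), 40, 40)
  pq <- segmentation_params(threshold = 0.8, threshold_mode = "quantile")
  f1 <- area_fraction(img2, pq)
  f2 <- area_fraction(img2 * 37.5, pq)
  expect_equal(f1$fraction, f2$fraction)
  # empty region flagged
  region3 <- region; region3[region3 == 2L] <- 0L
  attr(region3, "levels") <- c("SN", "NR")
  fr3 <- area_fraction(img, p, region3)
  expect_true(fr3$flagged[fr3$region == "NR"])
  expect_true(is.na(fr3$fraction[fr3$region == "NR"]))
})

test_that("skeleton branching: plus sign, straight bar, and the
           neighbour-count oracle on every skeleton <= 64x64", {
  plus <- matrix(FALSE, 31, 31)
  plus[14:18, 4:28] <- TRUE
  plus[4:28, 14:18] <- TRUE
  sk <- skeleton_branching(plus)
  expect_equal(sk$branch_points, 1)
  expect_equal(sk$endpoints, 4)

  bar <- matrix(FALSE, 20, 60); bar[9:12, 5:55] <- TRUE
  sb <- skeleton_branching(bar)
  expect_equal(sb$branch_points, 0)
  expect_equal(sb$endpoints, 2)

  # oracle: crossing_oracle() from helper-fixtures.R (brute-force
  # circular-transition count per skeleton pixel)
  set.seed(77)
  for (rep in 1:4) {
    st <- simulate_images(sim_image_config(
      width = 64, height = 64, channels = "IBA1",
      n_cells_per_channel = 1, branch_count = sample(0:5, 1),
      soma_radius = 5, process_length = 12, seed = 700 + rep))
    mask <- st$masks$IBA1 > 0
    skel <- prune_spurs(thin_skeleton(mask), 3)
    orc <- crossing_oracle(skel)
    got <- skeleton_branching(mask)
    expect_identical(c(got$branch_points, got$endpoints), as.integer(orc))
  }
  expect_equal(nrow(skeleton_branching(matrix(FALSE, 5, 5))), 0)
})

test_that("measured branching is strictly monotone in planted
           branch_count", {
  means <- sapply(c(0, 2, 4, 6), function(k) {
    st <- simulate_images(sim_image_config(
      channels = "IBA1", n_cells_per_channel = 8, branch_count = k,
      seed = 80 + k))
    sk <- skeleton_branching(segment_bright(
      st$channels$IBA1,
      segmentation_params(gaussian_sigma = 1, threshold = 7000,
                          min_object_px = 20)))
    mean(sk$branch_points)
  })
  expect_true(all(diff(means) > 0))
  expect_equal(cor(means, c(0, 2, 4, 6), method = "spearman"), 1)
})

test_that("per-individual summaries and group comparison behave", {
  recs <- data.frame(individual = c("i1", "i1", "i2", "i2", "i3", "i4"),
                     condition = rep(c("case", "control"), c(4, 2)),
                     region = "SN",
                     area_px = c(10, 30, 20, 40, 15, 25))
  s <- per_individual_summary(recs, metrics = "area_px")
  expect_equal(s$area_px[s$individual == "i1" & s$region == "all"], 20)
  # pooling invariance: duplicating records leaves means unchanged
  s2 <- per_individual_summary(rbind(recs, recs), metrics = "area_px")
  expect_equal(s$area_px, s2$area_px)
  # group comparison basics
  summ <- data.frame(individual = sprintf("i%d", 1:6),
                     condition = rep(c("case", "control"), each = 3),
                     region = "all",
                     branching_index = c(1, 2, 1.5, 5, 6, 5.5))
  gc <- group_compare(summ, "branching_index")
  expect_lt(gc$mean_case, gc$mean_control)
  expect_lt(gc$p, 0.05)
  # identical groups give t = 0; swapping labels flips the sign
  summ0 <- summ; summ0$branching_index <- rep(c(1, 2, 3), 2)
  expect_equal(group_compare(summ0, "branching_index")$t, 0)
  swapped <- summ
  swapped$condition <- ifelse(summ$condition == "case", "control", "case")
  expect_equal(group_compare(swapped, "branching_index")$t,
               -gc$t)
  expect_error(group_compare(summ[1:3, ], "branching_index"),
               "2 individuals")
})

test_that("TIFF round trip preserves 16-bit payloads", {
  set.seed(78)
  img <- matrix(sample.int(65535, 300) - 1L, 15, 20)
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(img, path)
  back <- read_tiff(path)
  expect_identical(back, img)
  img8 <- matrix(sample.int(255, 64) - 1L, 8, 8)
  write_tiff(img8, path, bits = 8)
  expect_identical(read_tiff(path), img8)
})
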