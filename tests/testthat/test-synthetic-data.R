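test_that("config validation rejects broken simplexes and rare fractions", {
  p <- snmidbrain:::.sn_default_proportions(
    snmidbrain:::.sn_default_types(12)$regular)
  bad <- p
  bad$case[1] <- bad$case[1] + 0.01
  expect_error(sim_counts_config(base_proportions = bad), "case")
  expect_error(sim_counts_config(rare_cluster_fraction = 0.5,
                                 rare_parent = "DaN"),
               "parent")
})

test_that("rare_cluster_fraction = 0 plants no rare barcodes", {
  a <- simulate_counts(small_cfg(
    n_samples = 2, conditions = c("control", "case"),
    n_cells_per_sample = 100, n_genes = 200,
    rare_cluster_fraction = 0, seed = 2))
  expect_false("CADPS2high" %in% a$barcode_meta$cell_type)
})

test_that("rare cluster is case-exclusive", {
  a <- small_assay(seed = 3, n_cells = 300)
  rare <- a$barcode_meta$cell_type == "CADPS2high" &
    !a$barcode_meta$is_doublet
  expect_true(all(a$barcode_meta$condition[rare] == "case"))
})

test_that("doublet fraction is within 2 binomial SD of the rate", {
  rate <- 0.1
  n <- 5000
  a <- simulate_counts(small_cfg(
    n_samples = 2, conditions = c("control", "case"),
    n_cells_per_sample = n / 2, n_genes = 150, doublet_rate = rate,
    seed = 7))
  frac <- mean(a$barcode_meta$is_doublet)
  expect_lt(abs(frac - rate), 2 * sqrt(rate * (1 - rate) / n) + 1e-9)
})

test_that("two runs with the same seed are identical; seeds differ", {
  cfg <- small_cfg(n_samples = 2, conditions = c("control", "case"),
                   n_cells_per_sample = 50, n_genes = 100, seed = 9)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$barcode_meta, b$barcode_meta)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(as.matrix(a$counts),
                         as.matrix(simulate_counts(cfg2)$counts)))
})

test_that("singlet library sizes stay inside libsize_range", {
  a <- simulate_counts(small_cfg(
    n_samples = 2, conditions = c("control", "case"),
    n_cells_per_sample = 80, n_genes = 150,
    libsize_range = c(1000, 4000), doublet_rate = 0.05, seed = 4))
  lib <- Matrix::colSums(a$counts)
  singlet <- !a$barcode_meta$is_doublet
  expect_true(all(lib[singlet] >= 1000 & lib[singlet] <= 4000))
})

test_that("truth JSON is written next to the data", {
  a <- small_assay(seed = 8, n_cells = 20, n_genes = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(a, path)
  tr <- jsonlite::read_json(path)
  expect_equal(tr$rare_type, "CADPS2high")
  expect_true(abs(Reduce(`+`, tr$base_proportions$case) - 1) < 1e-9)
})

test_that("trajectory simulator: degenerate 2-node tree gives segment
           position as pseudotime", {
  cfg <- sim_trajectory_config(
    n_cells = 200, branch_topology = rbind(c(1, 2)),
    node_coords = rbind(c(0, 0), c(10, 0)), root_node = 1,
    branch_tip_labels = c(`2` = "activated"), n_genes = 50,
    n_trajectory_genes = 10, embedding_noise_sd = 0, seed = 3)
  tr <- simulate_trajectory(cfg)
  # on a single horizontal segment pseudotime equals the x coordinate
  expect_equal(tr$barcode_meta$pseudotime_true, tr$barcode_meta$umap_1,
               tolerance = 1e-8)
})

test_that("condition_shift = 0 leaves case/control pseudotime equal in law", {
  tr <- simulate_trajectory(sim_trajectory_config(
    n_cells = 2000, condition_shift = 0, n_genes = 30,
    n_trajectory_genes = 5, seed = 11))
  pt <- tr$barcode_meta$pseudotime_true
  ks <- suppressWarnings(
    stats::ks.test(pt[tr$barcode_meta$condition == "case"],
                   pt[tr$barcode_meta$condition == "control"]))
  expect_gt(ks$p.value, 0.001)
})

test_that("flat gene profile gives Moran's I near its null expectation", {
  tr <- simulate_trajectory(sim_trajectory_config(
    n_cells = 300, n_genes = 40, n_trajectory_genes = 5, seed = 13))
  W <- knn_weight_matrix(cbind(tr$barcode_meta$umap_1,
                               tr$barcode_meta$umap_2), k = 10)
  flat <- as.matrix(tr$counts)[30:40, ]
  mi <- morans_i(W, log1p(flat))
  n <- ncol(flat)
  # flat genes: I scattered around -1/(n-1), far below trajectory genes
  expect_lt(abs(mean(mi$I)), 0.05)
  traj <- morans_i(W, log1p(as.matrix(tr$counts)[1:5, ]))
  expect_gt(min(traj$I), 0.05)
})

test_that("trajectory simulator rejects bad trees and roots", {
  expect_error(sim_trajectory_config(
    branch_topology = rbind(c(1, 2), c(3, 4)),
    node_coords = matrix(0, 4, 2)), "tree")
  expect_error(sim_trajectory_config(root_node = 99), "root")
})

test_that("image simulator: zero channels rejected, truth masks aligned", {
  expect_error(sim_image_config(channels = character(0)), "zero channels")
  st <- simulate_images(sim_image_config(
    channels = c("IBA1", "NM"), n_cells_per_channel = 3, seed = 5))
  expect_named(st$channels, c("IBA1", "NM"))
  expect_equal(dim(st$masks$IBA1), dim(st$channels$IBA1))
  tr <- attr(st, "truth")$objects
  # mask pixel counts match the truth table areas exactly
  for (ch in c("IBA1", "NM")) {
    sub <- tr[tr$channel == ch, ]
    expect_equal(tabulate(st$masks[[ch]], nbins = max(sub$object)),
                 sub$area_px)
  }
  # NM objects are darker than background, IBA1 brighter
  bg <- 2000
  expect_lt(mean(st$channels$NM[st$masks$NM > 0]), bg)
  expect_gt(mean(st$channels$IBA1[st$masks$IBA1 > 0]), bg)
})

test_that("single disc truth area is within 2% of pi r^2", {
  st <- simulate_images(sim_image_config(
    channels = "TH", n_cells_per_channel = 1, soma_radius = 10,
    noise_sd = 0, seed = 21))
  tr <- attr(st, "truth")$objects
  expect_lt(abs(tr$area_px - pi * 100) / (pi * 100), 0.02)
})

test_that("branch_count = 0 everywhere gives zero measured branching", {
  st <- simulate_images(sim_image_config(
    channels = "IBA1", n_cells_per_channel = 4, branch_count = 0,
    seed = 6))
  sk <- skeleton_branching(st$masks$IBA1 > 0)
  expect_true(all(sk$branch_points == 0))
})

test_that("same seed gives byte-identical TIFF payloads", {
  cfg <- sim_image_config(channels = "TH", n_cells_per_channel = 2,
                          seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_channel_stack(simulate_images(cfg), d1)
  write_channel_stack(simulate_images(cfg), d2)
  f1 <- readBin(file.path(d1, "TH.tif"), "raw", 1e7)
  f2 <- readBin(file.path(d2, "TH.tif"), "raw", 1e7)
  expect_identical(f1, f2)
})

test_that("gene stats: z and p are a consistent inverse pair", {
  gs <- simulate_gene_stats(sim_gene_stats_config(n_genes = 500, seed = 3))
  expect_lt(max(abs(p_to_z(gs$genes$p) - gs$genes$z)), 1e-10)
  expect_error(sim_gene_stats_config(delta = -1), "delta")
  expect_error(sim_gene_stats_config(set_sizes = 1e6), "set sizes")
})
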