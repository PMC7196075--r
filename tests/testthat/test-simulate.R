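test_that("fixed seed reproduces count matrices exactly", {
  cfg <- sim_config(n_cells_per_cluster = c(vEC = 5, HEC = 5), n_genes = 250,
                    depth_range = c(1000, 3000), seed = 9)
  a <- simulate_count_dataset(cfg)
  b <- simulate_count_dataset(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$planted_phase, b$truth$planted_phase)
})

test_that("per-cell totals respect the configured depth bounds", {
  sim <- default_sim()
  totals <- Matrix::colSums(sim$counts)
  expect_true(all(totals >= 1e5 & totals <= 3e6))
})

test_that("molecule table totals match the count matrix per cell", {
  fx <- small_tracked_sim()
  mt <- fx$sim$truth$molecule_table
  mt <- mt[!startsWith(mt$gene, "mt-"), ]
  per_cell <- table(factor(mt$cell, levels = colnames(fx$sim$counts)))
  expect_equal(as.integer(per_cell),
               unname(Matrix::colSums(fx$sim$counts)))
  # every molecule-table cell is a known cell, UMIs are 8-nt ACGT
  expect_true(all(mt$cell %in% names(fx$sim$truth$cell_cluster)))
  expect_true(all(grepl("^[ACGT]{8}$", mt$umi)))
})

test_that("planted fold changes are recovered by naive group-mean ratios", {
  # pick plant genes of moderate abundance (the fold calibration presumes a
  # plant does not dominate the cell's transcriptome); the baseline draw is
  # seed-determined, so a pilot run identifies the same baselines
  base_cfg <- sim_config(n_cells_per_cluster = c(A = 200, B = 200),
                         n_genes = 1000, marker_effect = 1, seed = 21)
  pilot <- simulate_count_dataset(base_cfg)$truth$gene_table
  pool <- pilot$gene[pilot$role == "filler" & pilot$baseline_tpm > 20 &
                       pilot$baseline_tpm < 500]
  plants <- head(pool, 20)
  cfg <- sim_config(
    n_cells_per_cluster = c(A = 200, B = 200), n_genes = 1000,
    marker_effect = 1,
    planted_de = data.frame(gene = plants, cluster = "A", fold = 4),
    seed = 21
  )
  sim <- simulate_count_dataset(cfg)
  tpm <- sweep(as.matrix(sim$counts), 2, Matrix::colSums(sim$counts), "/") * 1e6
  in_a <- sim$truth$cell_cluster == "A"
  ratio <- rowMeans(tpm[plants, in_a]) / rowMeans(tpm[plants, !in_a])
  expect_true(all(abs(ratio / 4 - 1) < 0.2))
})

test_that("a no-signal configuration yields a null dataset", {
  cfg <- sim_config(n_cells_per_cluster = c(A = 30, B = 30), n_genes = 500,
                    marker_effect = 1, seed = 5)
  sim <- simulate_count_dataset(cfg)
  norm <- normalize_tpm_log(sim$counts)
  lab <- names(sim$truth$cell_cluster)
  deg <- wilcoxon_deg(norm, lab[sim$truth$cell_cluster == "A"],
                      lab[sim$truth$cell_cluster == "B"])
  expect_equal(sum(deg$significant), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cells_per_cluster = c(A = 0)), "positive")
  expect_error(sim_config(marker_effect = 0.5), "marker_effect")
  expect_error(sim_config(proliferative_fraction = c(HEC = 1.5)), "fractions")
  expect_error(sim_config(depth_range = c(100, 50)), "depth_range")
  expect_error(
    sim_config(n_cells_per_cluster = c(X = 10),
               cluster_programs = list(X = c(nonexistent_panel = 4))),
    "unknown marker panel")
})

test_that("FASTQ output is deterministic and one read pair per copy", {
  fx <- small_tracked_sim()
  cfg <- fx$cfg
  cfg$pcr_duplication_mean <- 1  # exactly one read per molecule
  f1 <- tempfile(fileext = ".fq.gz"); f2 <- tempfile(fileext = ".fq.gz")
  reads <- simulate_fastq(fx$sim$truth, cfg, fastq1 = f1, fastq2 = f2)
  expect_equal(nrow(reads), nrow(fx$sim$truth$molecule_table))
  g1 <- tempfile(fileext = ".fq.gz"); g2 <- tempfile(fileext = ".fq.gz")
  simulate_fastq(fx$sim$truth, cfg, fastq1 = g1, fastq2 = g2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(g1)))
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(g2)))
})

test_that("barcode collisions are rejected", {
  fx <- small_tracked_sim()
  bad <- fx$sim$truth$barcodes
  bad[2] <- bad[1]
  expect_error(
    simulate_fastq(fx$sim$truth, fx$cfg, barcode_map = bad,
                   fastq1 = tempfile(), fastq2 = tempfile()),
    "collision")
})

test_that("trajectory generator plants the requested profiles", {
  tr0 <- simulate_trajectory_patterns(n_genes = 100, noise_sd = 0,
                                      seed = 3)
  # noiseless: genes of the same pattern have identical profiles
  prof <- cluster_profiles(tr0$norm, tr0$clusters)
  for (p in unique(tr0$truth$planted_pattern)) {
    members <- names(tr0$truth$planted_pattern)[tr0$truth$planted_pattern == p]
    expect_lt(max(apply(prof[members, , drop = FALSE], 2, sd)), 1e-12)
  }
  expect_error(simulate_trajectory_patterns(cluster_names = c("a", "b", "c"),
                                            n_profiles = 5),
               "fewer ordered clusters")
})
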