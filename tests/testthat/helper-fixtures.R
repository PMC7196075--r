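# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The reference synthetic embryo-like dataset used across modules.
default_sim <- function() {
  fixture("sim42", function() simulate_count_dataset(sim_config(seed = 42)))
}

default_qc <- function() {
  fixture("qc42", function() qc_normalize(default_sim()$counts))
}

truth_labels <- function(norm) {
  sim <- default_sim()
  stats::setNames(sim$truth$cell_cluster[colnames(norm)], colnames(norm))
}

# A small tracked simulation suitable for FASTQ round trips.
small_tracked_sim <- function() {
  fixture("sim_small", function() {
    cfg <- sim_config(
      n_cells_per_cluster = c(vEC = 8, earlyAEC = 8, HEC = 8, HC = 6, Neg = 6),
      n_genes = 300, depth_range = c(500, 2000), pcr_duplication_mean = 3,
      track_molecules = TRUE, seed = 11
    )
    list(cfg = cfg, sim = simulate_count_dataset(cfg))
  })
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Accuracy of a clustering against planted labels after majority mapping.
mapped_accuracy <- function(assigned, planted) {
  tab <- table(assigned, planted)
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  mean(map[as.character(assigned)] == planted)
}

# Cluster-mean profile matrix (genes x clusters) in cluster order.
cluster_profiles <- function(norm, labels, order = unique(labels)) {
  prof <- sapply(order, function(cl)
    rowMeans(norm[, labels[colnames(norm)] == cl, drop = FALSE]))
  matrix(prof, nrow = nrow(norm), dimnames = list(rownames(norm), order))
}
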