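three_cluster_norm <- function(shift = c(0, 0, 0), n = 12, n_genes = 5,
                               seed = 2) {
  set.seed(seed)
  labels <- stats::setNames(rep(c("k1", "k2", "k3"), each = n),
                            sprintf("c%03d", 1:(3 * n)))
  norm <- matrix(abs(rnorm(n_genes * 3 * n, 2, 0.3)), n_genes,
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                 names(labels)))
  for (i in 1:3) norm[1, labels == paste0("k", i)] <-
    norm[1, labels == paste0("k", i)] + shift[i]
  list(norm = norm, labels = labels)
}

test_that("ANOVA/Tukey finds planted shifts and respects the null", {
  null <- three_cluster_norm()
  d0 <- anova_tukey_deg(null$norm, null$labels)
  expect_length(d0$genes, 0)
  planted <- three_cluster_norm(shift = c(0, 3, 6), seed = 4)
  d1 <- anova_tukey_deg(planted$norm, planted$labels)
  expect_equal(d1$genes, "g01")
  pw <- d1$pairwise[d1$pairwise$gene == "g01" & d1$pairwise$changed, ]
  expect_true(all(pw$direction[pw$cluster_1 == "k3"] == "up"))
  # zero-variance genes are skipped with a note
  flat <- planted$norm
  flat[2, ] <- 1
  d2 <- anova_tukey_deg(flat, planted$labels)
  expect_equal(d2$skipped, "g02")
})

test_that("Tukey adjusted P is at least the unadjusted pairwise contrast P", {
  x <- three_cluster_norm(shift = c(0, 1, 2), seed = 9)
  d <- anova_tukey_deg(x$norm, x$labels, alpha = 1, fc = 1)
  cl <- factor(x$labels)
  n <- table(cl)
  for (g in unique(d$pairwise$gene)) {
    # pooled-variance ANOVA contrast P for each pair
    fit <- stats::aov(x$norm[g, ] ~ cl)
    mse <- summary(fit)[[1]][["Mean Sq"]][2]
    df <- fit$df.residual
    m <- tapply(x$norm[g, ], cl, mean)
    pw <- d$pairwise[d$pairwise$gene == g, ]
    for (i in seq_len(nrow(pw))) {
      se <- sqrt(mse * (1 / n[pw$cluster_1[i]] + 1 / n[pw$cluster_2[i]]))
      tstat <- (m[pw$cluster_1[i]] - m[pw$cluster_2[i]]) / se
      raw_p <- 2 * stats::pt(-abs(tstat), df)
      expect_gte(pw$p_adj[i], raw_p - 1e-12)
    }
  }
})

test_that("the eight directional classes are exclusive and exhaustive", {
  cls <- pattern_classes()
  expect_equal(nrow(cls), 8)
  expect_equal(anyDuplicated(paste(cls$branch1, cls$branch2)), 0)
  dirs <- c("up", "down", "unchanged")
  all_pairs <- expand.grid(b1 = dirs, b2 = dirs, stringsAsFactors = FALSE)
  admissible <- !(all_pairs$b1 == "unchanged" & all_pairs$b2 == "unchanged")
  expect_setequal(paste(cls$branch1, cls$branch2),
                  paste(all_pairs$b1, all_pairs$b2)[admissible])
})

test_that("directional pattern assignment maps direction pairs correctly", {
  pairwise <- data.frame(
    gene = rep(c("up_unch", "both_unch", "down_up"), each = 2),
    cluster_1 = rep(c("lateAEC", "HEC"), 3),
    cluster_2 = "earlyAEC",
    p_adj = c(0.001, 0.9, 0.9, 0.9, 0.001, 0.001),
    fold = c(4, 1.1, 1.0, 1.0, 0.2, 3),
    changed = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    direction = c("up", "up", "up", "up", "down", "up"),
    stringsAsFactors = FALSE
  )
  pairwise$pair <- paste0(pairwise$cluster_1, "-", pairwise$cluster_2)
  out <- assign_directional_patterns(pairwise, "earlyAEC", "lateAEC", "HEC")
  expect_setequal(out$gene, c("up_unch", "down_up"))  # both-unchanged rejected
  expect_equal(out$dir_branch1[out$gene == "up_unch"], "up")
  expect_equal(out$dir_branch2[out$gene == "up_unch"], "unchanged")
  expect_equal(out$dir_branch1[out$gene == "down_up"], "down")
  expect_equal(out$dir_branch2[out$gene == "down_up"], "up")
  cls <- pattern_classes()
  expect_equal(out$pattern[out$gene == "down_up"],
               cls$pattern[cls$branch1 == "down" & cls$branch2 == "up"])
  # reversed pair orientation (reference-branch) flips the direction
  rev_pair <- pairwise[1, ]
  rev_pair$cluster_1 <- "earlyAEC"; rev_pair$cluster_2 <- "lateAEC"
  rev_pair$direction <- "down"
  out2 <- assign_directional_patterns(rbind(rev_pair, pairwise[2:6, ]),
                                      "earlyAEC", "lateAEC", "HEC")
  expect_equal(out2$dir_branch1[out2$gene == "up_unch"], "up")
})

test_that("planted directional patterns are recovered from the synthetic dataset", {
  qc <- default_qc()
  labels <- truth_labels(qc$norm)
  cells <- names(labels)[labels %in% c("earlyAEC", "lateAEC", "HEC")]
  sim <- default_sim()
  sig <- sim$truth$gene_table$gene[sim$truth$gene_table$role == "signature"]
  deg <- anova_tukey_deg(qc$norm[, cells], labels[cells],
                         genes = c(sig, "Gene00001"))
  out <- assign_directional_patterns(
    deg$pairwise[deg$pairwise$gene %in% deg$genes, ],
    "earlyAEC", "lateAEC", "HEC")
  # HEC-exclusive plants: unchanged in lateAEC, up in HEC
  expect_true(all(sig %in% out$gene))
  expect_true(all(out$dir_branch2[out$gene %in% sig] == "up"))
  expect_true(all(out$dir_branch1[out$gene %in% sig] == "unchanged"))
})

test_that("consensus clustering is deterministic with valid consensus values", {
  tr <- simulate_trajectory_patterns(n_genes = 120, noise_sd = 0.2, seed = 7)
  prof <- cluster_profiles(tr$norm, tr$clusters)
  c1 <- consensus_pattern_clusters(prof, k = 5, reps = 40, seed = 7)
  c2 <- consensus_pattern_clusters(prof, k = 5, reps = 40, seed = 7)
  expect_identical(c1$clusters, c2$clusters)
  expect_true(all(c1$consensus >= 0 & c1$consensus <= 1))
  expect_equal(unname(diag(c1$consensus)), rep(1, nrow(prof)))
  # noiseless plants are recovered exactly
  tr0 <- simulate_trajectory_patterns(n_genes = 100, noise_sd = 0, seed = 8)
  prof0 <- cluster_profiles(tr0$norm, tr0$clusters)
  c0 <- consensus_pattern_clusters(prof0, k = 5, reps = 40, seed = 8)
  expect_equal(ari(c0$clusters, tr0$truth$planted_pattern), 1)
  expect_error(consensus_pattern_clusters(prof0[1:3, ], k = 5), "more clusters")
})

test_that("correlation reassignment is self-consistent and affine-invariant", {
  tr <- simulate_trajectory_patterns(n_genes = 100, noise_sd = 0.1, seed = 15)
  prof <- cluster_profiles(tr$norm, tr$clusters)
  cons <- consensus_pattern_clusters(prof, k = 5, reps = 40, seed = 15)
  re <- reassign_by_correlation(prof, prof, cons$clusters)
  # member genes come back to their own pattern
  expect_gte(mean(re$pattern == cons$clusters[re$gene]), 0.95)
  # per-gene affine rescaling leaves assignments unchanged
  set.seed(16)
  prof2 <- prof * runif(nrow(prof), 0.5, 2) + runif(nrow(prof), -1, 1)
  re2 <- reassign_by_correlation(prof2, prof, cons$clusters)
  expect_equal(re$pattern, re2$pattern)
  # constant profiles are flagged unassigned
  flat <- rbind(prof, flatgene = rep(1, ncol(prof)))
  re3 <- reassign_by_correlation(flat, prof, cons$clusters)
  expect_true(is.na(re3$pattern[re3$gene == "flatgene"]))
})

test_that("Fisher overlap equals the hypergeometric tail and gates retention", {
  # fixed 2x2 table: overlap 10, regulon 20, pattern 20, universe 1000
  universe <- sprintf("u%04d", 1:1000)
  regulon <- universe[1:20]
  pattern <- universe[c(1:10, 101:110)]
  res <- regulon_overlap_test(list(r1 = regulon), pattern, universe)
  oracle <- sum(dhyper(10:20, 20, 980, 20))
  expect_lt(abs(res$p - oracle), 1e-10)
  expect_true(res$retained)
  # disjoint regulon is not retained
  res2 <- regulon_overlap_test(list(r = universe[900:920]), universe[1:10],
                               universe)
  expect_false(res2$retained)
  expect_error(regulon_overlap_test(list(r = "a"), "a", character()), "empty")
})

test_that("PC1 gene-set activity is sign-corrected toward mean expression", {
  set.seed(20)
  base <- rnorm(30, 3, 1)
  norm <- rbind(g1 = base, g2 = base * 1.5 + rnorm(30, 0, 0.01))
  colnames(norm) <- sprintf("c%02d", 1:30)
  act <- gene_set_activity_pc1(norm, c("g1", "g2"))
  expect_gt(cor(act, colMeans(norm)), 0.99)
  # property: activity correlates positively with the set mean
  for (i in 1:25) {
    set.seed(100 + i)
    m <- matrix(abs(rnorm(8 * 20, 2, 1)), 8,
                dimnames = list(paste0("g", 1:8), paste0("c", 1:20)))
    a <- gene_set_activity_pc1(m, rownames(m))
    expect_gt(cor(a, colMeans(m)), 0)
  }
  flat <- matrix(1, 2, 5, dimnames = list(c("a", "b"), paste0("c", 1:5)))
  expect_error(gene_set_activity_pc1(flat, c("a", "b")), "degenerate")
})

test_that("rolling smoothing averages over truncated centered windows", {
  expect_equal(rolling_smooth(c(1, 2, 3, 4, 5), window = 3),
               c(1.5, 2, 3, 4, 4.5))
  x <- rnorm(20)
  expect_equal(rolling_smooth(x, window = 1), x)
  expect_equal(rolling_smooth(rep(2, 15), window = 15), rep(2, 15))
  expect_error(rolling_smooth(numeric(0), integer(0), 3), "empty|window")
  expect_error(rolling_smooth(1:5, window = 9), "window")
})
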