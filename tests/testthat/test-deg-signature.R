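two_group_norm <- function(nA = 10, nB = 10, n_genes = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * (nA + nB), 2, 1)), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              c(sprintf("a%02d", seq_len(nA)),
                                sprintf("b%02d", seq_len(nB)))))
  m
}

test_that("identical groups produce no significant genes", {
  m <- two_group_norm()
  a <- colnames(m)[1:10]
  dup <- cbind(m[, a], m[, a])          # same cells twice under new names
  colnames(dup) <- c(a, paste0(a, "_copy"))
  deg <- wilcoxon_deg(dup, a, paste0(a, "_copy"), min_frac = 0)
  expect_equal(sum(deg$significant), 0)
  expect_true(all(deg$p_raw > 0.99))
})

test_that("group swap flips direction and preserves the statistics", {
  m <- two_group_norm(seed = 3)
  a <- colnames(m)[1:10]; b <- colnames(m)[11:20]
  d1 <- wilcoxon_deg(m, a, b, min_frac = 0)
  d2 <- wilcoxon_deg(m, b, a, min_frac = 0)
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d1$p_raw, d2$p_raw)
  expect_equal(d1$fold_change, 1 / d2$fold_change, tolerance = 1e-12)
  expect_true(all((d1$direction == "up") == (d2$direction == "down") |
                    d1$fold_change == 1))
})

test_that("multiple-testing adjustment preserves the raw P ordering", {
  m <- two_group_norm(seed = 5, n_genes = 100)
  d <- wilcoxon_deg(m, colnames(m)[1:10], colnames(m)[11:20], min_frac = 0)
  expect_true(all(d$p_adj >= d$p_raw))
  o <- order(d$p_raw)
  expect_true(all(diff(d$p_adj[o]) >= -1e-15))
})

test_that("AUC equals the exhaustive pairwise oracle, including ties", {
  xa <- c(3.1, 2.0, 2.0, 5.5, 0.0, 4.2)
  xb <- c(2.0, 1.0, 0.0, 3.1, 3.1, 2.7)
  m <- rbind(g1 = c(xa, xb))
  colnames(m) <- c(paste0("a", 1:6), paste0("b", 1:6))
  got <- auc_deg(m, paste0("a", 1:6), paste0("b", 1:6), min_frac = 0)
  oracle <- 0
  for (i in 1:6) for (j in 1:6) {
    oracle <- oracle + (xa[i] > xb[j]) + 0.5 * (xa[i] == xb[j])
  }
  expect_equal(got$auc, oracle / 36)
  # perfectly separated and all-tied genes hit the AUC extremes
  m2 <- rbind(sep = c(rep(5, 6), rep(1, 6)), const = rep(2, 12))
  colnames(m2) <- colnames(m)
  g2 <- auc_deg(m2, paste0("a", 1:6), paste0("b", 1:6), min_frac = 0)
  expect_equal(g2[g2$gene == "sep", "auc"], 1)
  expect_equal(g2[g2$gene == "sep", "power"], 1)
  expect_equal(g2[g2$gene == "const", "auc"], 0.5)
  expect_equal(g2[g2$gene == "const", "power"], 0)
})

test_that("overrepresentation requires up-regulation against every cluster", {
  # gene up in target vs 3 of 4 clusters only -> excluded
  set.seed(6)
  n <- 30
  labels <- stats::setNames(rep(c("T", "o1", "o2", "o3", "o4"), each = n),
                            sprintf("c%03d", 1:(5 * n)))
  norm <- matrix(abs(rnorm(20 * 5 * n, 2, 0.3)), 20,
                 dimnames = list(sprintf("g%02d", 1:20), names(labels)))
  norm["g01", labels == "T"] <- norm["g01", labels == "T"] + 4   # up vs all
  norm["g02", labels %in% c("T", "o4")] <-
    norm["g02", labels %in% c("T", "o4")] + 4                    # not vs o4
  hits <- find_overrepresented(norm, labels, "T", c("o1", "o2", "o3", "o4"))
  expect_equal(hits, "g01")
  # anti-monotone in the comparison set
  hits3 <- find_overrepresented(norm, labels, "T", c("o1", "o2", "o3"))
  expect_true(all(hits %in% hits3))
  expect_setequal(hits3, c("g01", "g02"))
})

test_that("signature screen drops EMP, low-target and ubiquitous genes with reasons", {
  sim <- default_sim()
  qc <- default_qc()
  labels <- truth_labels(qc$norm)
  plants <- sim$truth$gene_table
  sig <- plants$gene[plants$role == "signature"]
  emp <- plants$gene[plants$role == "emp"]
  ubiq <- plants$gene[plants$role == "ubiquitous"]
  candidates <- c(sig, emp, ubiq)
  res <- screen_signature(candidates, qc$norm, labels)
  expect_setequal(res$signature, sig)
  expect_setequal(res$reasons$gene[res$reasons$reason == "EMP exclusion"], emp)
  expect_setequal(
    res$reasons$gene[res$reasons$reason == "highly expressed in every cluster"],
    ubiq)
  # stages are nested
  st <- res$stages
  expect_true(all(st$after_emp %in% st$candidates))
  expect_true(all(st$after_target_expression %in% st$after_emp))
  expect_true(all(st$signature %in% st$after_target_expression))
})

test_that("reference-gene correlation ranks co-expressed modules on top", {
  set.seed(12)
  n <- 60
  ref <- rnorm(n, 3, 1)
  norm <- rbind(
    Runx1 = ref,
    mod1 = ref + rnorm(n, 0, 0.2),
    mod2 = ref + rnorm(n, 0, 0.2),
    anti = max(ref) - ref,
    noise1 = rnorm(n, 3, 1), noise2 = rnorm(n, 3, 1)
  )
  colnames(norm) <- sprintf("c%02d", 1:n)
  out <- correlate_with_reference(norm, colnames(norm), "Runx1")
  expect_equal(out$gene[1], "Runx1")
  expect_equal(out$r[1], 1)
  expect_setequal(out$gene[2:3], c("mod1", "mod2"))
  expect_equal(out$gene[nrow(out)], "anti")
  expect_equal(out$r[out$gene == "anti"], -1)
  expect_error(correlate_with_reference(rbind(norm, flat = rep(1, n)),
                                        colnames(norm), "flat"), "constant")
})

test_that("gene annotation flags TF and surfaceome membership", {
  # synthetic annotation lists
  ann <- annotate_genes(c("both", "tf_only", "surf_only", "neither"),
                        tf_list = c("both", "tf_only"),
                        surfaceome_list = c("both", "surf_only"))
  expect_equal(ann$is_tf, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ann$is_surface, c(TRUE, FALSE, TRUE, FALSE))
})
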