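#' Multi-cluster differential expression by ANOVA + Tukey HSD
#'
#' Per gene, a one-way ANOVA across clusters followed by Tukey's honest
#' significant difference test for every cluster pair. A pair is "changed"
#' when its Tukey-adjusted P is below `alpha` and the de-logged mean fold is
#' above `fc` or below 1/`fc`; a gene is retained when any pair changed.
#' Zero-variance genes are skipped and listed.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels named cluster vector (>= 3 clusters, each >= 3 cells).
#' @param alpha adjusted-P threshold (default 0.05, strict <).
#' @param fc fold threshold (default 2, strict >).
#' @param genes optional subset of genes to test (default all rows).
#' @return list with `genes` (retained gene vector, ordered by minimum
#'   adjusted P), `pairwise` (data.frame gene/pair/cluster_1/cluster_2/
#'   p_adj/fold/changed/direction), `anova_p` (named vector),
#'   `skipped` (zero-variance genes).
#' @export
anova_tukey_deg <- function(norm, labels, alpha = 0.05, fc = 2,
                            genes = rownames(norm)) {
  labels <- labels[colnames(norm)]
  cl <- factor(labels)
  if (nlevels(cl) < 3) stop("need at least three clusters")
  if (any(table(cl) < 3)) stop("every cluster needs at least three cells")
  skipped <- character()
  rows <- list()
  anova_p <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    x <- norm[g, ]
    if (stats::sd(x) == 0) {
      skipped <- c(skipped, g)
      next
    }
    fit <- stats::aov(x ~ cl)
    anova_p[g] <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$cl
    pair <- rownames(tk)
    halves <- strsplit(pair, "-", fixed = TRUE)
    c1 <- vapply(halves, `[`, "", 1)
    c2 <- vapply(halves, `[`, "", 2)
    m <- tapply(2^x - 1, cl, mean)
    fold <- (m[c1] + 0.01) / (m[c2] + 0.01)
    changed <- tk[, "p adj"] < alpha & (fold > fc | fold < 1 / fc)
    rows[[g]] <- data.frame(
      gene = g, pair = pair, cluster_1 = c1, cluster_2 = c2,
      p_adj = tk[, "p adj"], fold = unname(fold), changed = unname(changed),
      direction = ifelse(fold >= 1, "up", "down"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  pairwise <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), pair = character(),
               cluster_1 = character(), cluster_2 = character(),
               p_adj = numeric(), fold = numeric(), changed = logical(),
               direction = character())
  hit <- tapply(pairwise$changed, pairwise$gene, any)
  retained <- names(hit)[hit]
  minp <- tapply(pairwise$p_adj, pairwise$gene, min)
  retained <- retained[order(minp[retained])]
  list(genes = retained, pairwise = pairwise, anova_p = anova_p,
       skipped = skipped)
}

# The eight admissible (branch1, branch2) direction pairs relative to the
# reference cluster, in canonical order: branch1 direction major (up, down,
# unchanged), branch2 minor, the doubly-unchanged pair excluded.
#' Enumerate the directional pattern classes
#'
#' Two branch-versus-reference comparisons with three outcomes each (up,
#' down, unchanged) give 3 x 3 - 1 = 8 admissible classes once the
#' doubly-unchanged pair is excluded.
#'
#' @return data.frame `pattern` (P1..P8), `branch1`, `branch2`.
#' @export
pattern_classes <- function() {
  dirs <- c("up", "down", "unchanged")
  grid <- expand.grid(branch2 = dirs, branch1 = dirs,
                      stringsAsFactors = FALSE)[, c("branch1", "branch2")]
  grid <- grid[!(grid$branch1 == "unchanged" & grid$branch2 == "unchanged"), ]
  grid$pattern <- paste0("P", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid[, c("pattern", "branch1", "branch2")]
}

#' Assign DEGs to the eight directional patterns
#'
#' Genes are classified by their change direction in each of two branch
#' clusters relative to a reference cluster (from the Tukey pairwise table).
#' A gene must be changed in at least one of the two comparisons; genes
#' unchanged in both are rejected.
#'
#' @param pairwise pairwise table from [anova_tukey_deg()].
#' @param reference,branch1,branch2 cluster names.
#' @return data.frame `gene`, `dir_branch1`, `dir_branch2`, `pattern`.
#' @export
assign_directional_patterns <- function(pairwise, reference, branch1,
                                        branch2) {
  dir_vs_ref <- function(branch) {
    sel <- (pairwise$cluster_1 == branch & pairwise$cluster_2 == reference) |
      (pairwise$cluster_1 == reference & pairwise$cluster_2 == branch)
    p <- pairwise[sel, , drop = FALSE]
    d <- ifelse(!p$changed, "unchanged",
         ifelse(p$cluster_1 == branch, p$direction,
                ifelse(p$direction == "up", "down", "up")))
    stats::setNames(d, p$gene)
  }
  d1 <- dir_vs_ref(branch1)
  d2 <- dir_vs_ref(branch2)
  genes <- intersect(names(d1), names(d2))
  keep <- !(d1[genes] == "unchanged" & d2[genes] == "unchanged")
  genes <- genes[keep]
  classes <- pattern_classes()
  key <- paste(classes$branch1, classes$branch2)
  pat <- stats::setNames(classes$pattern, key)
  data.frame(gene = genes, dir_branch1 = unname(d1[genes]),
             dir_branch2 = unname(d2[genes]),
             pattern = unname(pat[paste(d1[genes], d2[genes])]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus k-means clustering of gene expression profiles
#'
#' Repeatedly subsamples the genes, k-means-partitions the z-scored profiles,
#' and records how often each gene pair lands in the same cluster among the
#' runs where both were sampled. The consensus matrix is cut into `k` groups
#' by average-linkage hierarchical clustering. Deterministic for a fixed
#' seed.
#'
#' @param profiles genes x conditions matrix (e.g. per-cluster means of the
#'   top DEGs).
#' @param k number of patterns (default 5).
#' @param reps subsampling repetitions (default 100).
#' @param subsample fraction of genes per repetition (default 0.8).
#' @param seed RNG seed.
#' @return list with `clusters` (named integer vector), `consensus`
#'   (genes x genes matrix), `centroids` (k x conditions mean profiles).
#' @export
consensus_pattern_clusters <- function(profiles, k = 5, reps = 100,
                                       subsample = 0.8, seed = 1L) {
  n <- nrow(profiles)
  if (k > n) stop("more clusters than genes")
  z <- t(scale(t(profiles)))
  z[!is.finite(z)] <- 0
  local_seed(seed, {
    co <- matrix(0, n, n)
    both <- matrix(0, n, n)
    m <- max(k, floor(subsample * n))
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      km <- stats::kmeans(z[idx, , drop = FALSE], centers = k, nstart = 1,
                          iter.max = 50)
      same <- outer(km$cluster, km$cluster, "==")
      co[idx, idx] <- co[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
    consensus <- ifelse(both > 0, co / both, 0)
    diag(consensus) <- 1
    dimnames(consensus) <- list(rownames(profiles), rownames(profiles))
    tree <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
    clusters <- stats::cutree(tree, k = k)
    centroids <- t(sapply(seq_len(k), function(ki)
      colMeans(profiles[clusters == ki, , drop = FALSE])))
    rownames(centroids) <- paste0("pattern", seq_len(k))
    list(clusters = clusters, consensus = consensus, centroids = centroids)
  })
}

#' Reassign genes to the pattern with maximal average member correlation
#'
#' Every gene is assigned to the pattern whose member genes have the highest
#' average Pearson correlation with the gene's profile; ties break to the
#' lowest pattern id. Constant gene profiles come back unassigned (NA) and
#' flagged.
#'
#' @param profiles genes x conditions matrix of the genes to (re)assign.
#' @param member_profiles genes x conditions matrix of the pattern members.
#' @param membership named integer vector mapping member genes to patterns.
#' @return data.frame `gene`, `pattern` (integer, NA when unassignable),
#'   `mean_r`.
#' @export
reassign_by_correlation <- function(profiles, member_profiles, membership) {
  stopifnot(all(names(membership) %in% rownames(member_profiles)))
  k <- sort(unique(membership))
  sds <- apply(profiles, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(profiles), t(member_profiles)))
  mean_r <- sapply(k, function(ki) {
    members <- names(membership)[membership == ki]
    rowMeans(r[, members, drop = FALSE])
  })
  mean_r <- matrix(mean_r, nrow = nrow(profiles),
                   dimnames = list(rownames(profiles), paste0("pattern", k)))
  best <- apply(mean_r, 1, function(v)
    if (all(is.na(v))) NA_integer_ else k[which.max(v)])
  best[sds == 0] <- NA_integer_
  data.frame(gene = rownames(profiles), pattern = unname(best),
             mean_r = vapply(seq_len(nrow(mean_r)), function(i)
               if (is.na(best[i])) NA_real_ else
                 mean_r[i, paste0("pattern", best[i])], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher exact overlap test of regulons against a pattern gene set
#'
#' One-sided (enrichment) Fisher exact test of each regulon's overlap with
#' the pattern genes within the given universe; regulons with adjusted
#' P < `alpha` are flagged as retained.
#'
#' @param regulons named list of gene vectors (each a TF with its targets).
#' @param pattern_genes gene set to test against.
#' @param universe background gene universe (nonempty; both sides are
#'   intersected with it).
#' @param alpha significance threshold (default 0.05).
#' @param adjust multiple-testing method (default "BH").
#' @return data.frame `regulon`, `overlap`, `regulon_size`, `pattern_size`,
#'   `universe_size`, `odds_ratio`, `p`, `p_adj`, `retained`.
#' @export
regulon_overlap_test <- function(regulons, pattern_genes, universe,
                                 alpha = 0.05, adjust = "BH") {
  if (length(universe) == 0) stop("empty universe")
  pattern_genes <- intersect(pattern_genes, universe)
  rows <- lapply(names(regulons), function(nm) {
    reg <- intersect(regulons[[nm]], universe)
    a <- length(intersect(reg, pattern_genes))
    b <- length(reg) - a
    c <- length(pattern_genes) - a
    d <- length(universe) - a - b - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")
    data.frame(regulon = nm, overlap = a, regulon_size = length(reg),
               pattern_size = length(pattern_genes),
               universe_size = length(universe),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$retained <- out$p_adj < alpha
  out[order(out$p), ]
}

#' Gene-set activity as sign-corrected PC1 scores
#'
#' The activity of a gene set in each cell is the cell's score on the first
#' principal component of the set's expression submatrix, with the sign
#' flipped if necessary so the scores correlate positively with the per-cell
#' mean expression of the set.
#'
#' @param norm genes x cells normalized matrix.
#' @param gene_set genes of the set (>= 2 present).
#' @param cells cells to score (default all).
#' @return named numeric vector of per-cell activities.
#' @export
gene_set_activity_pc1 <- function(norm, gene_set, cells = colnames(norm)) {
  genes <- intersect(gene_set, rownames(norm))
  if (length(genes) < 2) stop("need at least two genes of the set")
  if (length(cells) < 3) stop("need at least three cells")
  x <- t(norm[genes, cells, drop = FALSE])
  if (all(apply(x, 2, stats::sd) == 0)) stop("degenerate (rank-0) submatrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  act <- pc$x[, 1]
  m <- rowMeans(x)
  if (stats::sd(m) > 0 && suppressWarnings(cor(act, m)) < 0) act <- -act
  act
}

#' Moving-average smoothing along an ordered set of cells
#'
#' Centered moving average with truncated windows at the edges, the smoothing
#' applied to expression heat maps over trajectory-ordered cells.
#'
#' @param values numeric vector (one value per cell).
#' @param order integer or name order of the cells along the trajectory.
#' @param window window size (>= 1, <= number of cells).
#' @return smoothed values, in trajectory order.
#' @export
rolling_smooth <- function(values, order = seq_along(values), window = 15) {
  if (length(order) == 0) stop("empty cell order")
  if (window < 1 || window > length(order))
    stop("window must lie between 1 and the number of cells")
  x <- values[order]
  zoo::rollapply(x, width = window, FUN = mean, partial = TRUE,
                 align = "center")
}
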