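#' Select highly variable genes
#'
#' A gene qualifies when its mean expression lies strictly between `mean_lo`
#' and `mean_hi` and its bin-standardized dispersion exceeds `disp_min`,
#' after removing the supplied cell-cycle exclusion list. Following the
#' convention of the era's single-cell toolkits, the mean is
#' log2(mean(2^x - 1) + 1) of the de-logged values and the dispersion is
#' variance/mean of the de-logged values, standardized within 20 bins of
#' gene mean. Standardization is robust (median and MAD per bin, the
#' cell-ranger flavour) so that a handful of strongly variable genes cannot
#' inflate a bin's baseline and mask other markers.
#'
#' Cell-cycle genes are excluded before the bin statistics are computed, not
#' merely dropped from the output list: proliferation programs are among the
#' most dispersed genes and would otherwise inflate the per-bin baseline that
#' other genes are standardized against, defeating the purpose of mitigating
#' the cell-cycle effect.
#'
#' @param norm genes x cells normalized matrix.
#' @param cc_go_genes genes to exclude (cell-cycle GO term members).
#' @param mean_lo,mean_hi,disp_min selection thresholds (defaults 1, 8, 1).
#' @param n_bins number of mean bins for dispersion standardization.
#' @return list with `genes` (the HVG set) and `stats` (per-gene mean,
#'   dispersion, standardized dispersion; excluded genes carry NA z).
#' @export
select_hvgs <- function(norm, cc_go_genes = character(), mean_lo = 1,
                        mean_hi = 8, disp_min = 1, n_bins = 20) {
  if (nrow(norm) == 0) stop("empty matrix")
  y <- 2^norm - 1
  mu_y <- rowMeans(y)
  gene_mean <- log2(mu_y + 1)
  v <- apply(y, 1, var)
  disp <- ifelse(mu_y > 0, v / mu_y, 0)
  eligible <- !(rownames(norm) %in% cc_go_genes)
  bins <- cut(gene_mean, breaks = n_bins, include.lowest = TRUE)
  z <- rep(NA_real_, nrow(norm))
  for (b in levels(bins)) {
    idx <- which(bins == b & eligible)
    if (!length(idx)) next
    s <- stats::mad(disp[idx])
    m <- stats::median(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
  }
  sel <- eligible & gene_mean > mean_lo & gene_mean < mean_hi &
    !is.na(z) & z > disp_min
  genes <- rownames(norm)[sel]
  list(genes = genes,
       stats = data.frame(gene = rownames(norm), mean = gene_mean,
                          dispersion = disp, dispersion_z = z,
                          hvg = rownames(norm) %in% genes,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' PCA embedding of cells on the HVG submatrix
#'
#' Genes are standardized (unit variance) before PCA on cells. Also returns
#' an elbow suggestion: the smallest number of components after which the
#' incremental variance explained drops below 1% of the total.
#'
#' @param norm genes x cells normalized matrix.
#' @param hvgs genes to embed on.
#' @param n_pcs number of components to return (default 15).
#' @return list with `scores` (cells x n_pcs), `var_explained` (fractions per
#'   component) and `elbow`.
#' @export
pca_embed <- function(norm, hvgs, n_pcs = 15) {
  x <- t(norm[hvgs, , drop = FALSE])
  if (n_pcs > min(dim(x))) stop("n_pcs exceeds the matrix rank bound")
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  elbow <- which(ve < 0.01)[1]
  elbow <- if (is.na(elbow)) length(ve) else max(elbow - 1L, 1L)
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       var_explained = ve, elbow = elbow)
}

#' Graph-based clustering of the PCA embedding
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance in the embedding)
#' and partitions it by Louvain modularity optimization; deterministic for a
#' fixed seed.
#'
#' @param embedding cells x PCs score matrix.
#' @param k neighbours per cell (default 20).
#' @param seed RNG seed for the community detection.
#' @return named character vector of cluster labels ("C1", "C2", ...).
#' @export
cluster_cells <- function(embedding, k = 20, seed = 0L) {
  n <- nrow(embedding)
  if (n < 2) stop("need at least two cells")
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(embedding))
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  })
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- local_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  stats::setNames(paste0("C", as.integer(memb)), rownames(embedding))
}

#' Reclassify clusters dominated by negative-control cells
#'
#' Any cluster whose fraction of flagged negative-control cells strictly
#' exceeds `threshold` is renamed to the negative cluster; a deterministic
#' replacement for the manual reclassification step. Cells in other clusters
#' are never moved.
#'
#' @param labels named cluster vector.
#' @param negative_control named logical vector flagging control cells.
#' @param threshold strict fraction threshold (default 0.5).
#' @param negative_cluster name given to reclassified clusters.
#' @return relabelled named vector.
#' @export
reclassify_negative_cluster <- function(labels, negative_control,
                                        threshold = 0.5,
                                        negative_cluster = "Neg") {
  stopifnot(all(names(labels) %in% names(negative_control)))
  frac <- tapply(negative_control[names(labels)], labels, mean)
  neg_clusters <- names(frac)[frac > threshold]
  labels[labels %in% neg_clusters] <- negative_cluster
  labels
}

#' Cluster-cluster correlation on mean HVG profiles
#'
#' Pearson correlation between per-cluster mean expression profiles of the
#' highly variable genes, with average-linkage hierarchical clustering on
#' 1 - r.
#'
#' @param norm genes x cells normalized matrix.
#' @param labels named cluster vector.
#' @param hvgs genes to profile on.
#' @return list with `r` (correlation matrix) and `tree` (hclust).
#' @export
cluster_correlation <- function(norm, labels, hvgs) {
  labels <- labels[colnames(norm)]
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least two clusters")
  sizes <- table(labels)
  if (any(sizes < 2))
    warning("clusters with fewer than 2 cells: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  prof <- sapply(cl, function(c)
    rowMeans(norm[hvgs, labels == c, drop = FALSE]))
  r <- stats::cor(prof)
  tree <- stats::hclust(stats::as.dist(1 - r), method = "average")
  list(r = r, tree = tree)
}
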