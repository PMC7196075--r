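#' Two-group differential expression by Wilcoxon rank-sum test
#'
#' Genes are gated on detection: at least `min_frac` of the cells of one of
#' the two groups must express the gene (nonzero). For gated genes a
#' two-sided rank-sum test is computed on the normalized values, with the
#' fold change taken as the ratio of group means of the de-logged values
#' (2^x - 1) plus a 0.01 pseudocount. Significance requires fold change >=
#' `fc_min` (in either direction) and adjusted P <= `alpha`.
#'
#' @param norm genes x cells normalized matrix.
#' @param cells_A,cells_B cell name vectors of the two groups (>= 3 each).
#' @param min_frac detection gate (default 0.25).
#' @param fc_min fold-change threshold (default 2).
#' @param alpha adjusted-P threshold (default 0.05).
#' @param adjust multiple-testing method: "bonferroni" (default) or "BH".
#' @return data.frame (DEGTable): `gene`, `mean_A`, `mean_B`, `frac_A`,
#'   `frac_B`, `fold_change`, `p_raw`, `p_adj`, `direction`, `significant`.
#' @export
wilcoxon_deg <- function(norm, cells_A, cells_B, min_frac = 0.25,
                         fc_min = 2, alpha = 0.05,
                         adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  if (length(cells_A) < 3 || length(cells_B) < 3)
    stop("both groups need at least three cells")
  a <- norm[, cells_A, drop = FALSE]
  b <- norm[, cells_B, drop = FALSE]
  frac_A <- rowMeans(a > 0)
  frac_B <- rowMeans(b > 0)
  gate <- pmax(frac_A, frac_B) >= min_frac
  genes <- rownames(norm)[gate]
  p_raw <- vapply(genes, function(g) {
    suppressWarnings(stats::wilcox.test(a[g, ], b[g, ])$p.value)
  }, numeric(1))
  p_raw[is.na(p_raw)] <- 1  # all-tied genes carry no evidence
  mean_A <- rowMeans(2^a[genes, , drop = FALSE] - 1)
  mean_B <- rowMeans(2^b[genes, , drop = FALSE] - 1)
  fold_change <- (mean_A + 0.01) / (mean_B + 0.01)
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  out <- data.frame(
    gene = genes, mean_A = mean_A, mean_B = mean_B,
    frac_A = frac_A[gate], frac_B = frac_B[gate],
    fold_change = fold_change, p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(fold_change >= 1, "up", "down"),
    significant = (fold_change >= fc_min | fold_change <= 1 / fc_min) &
      p_adj <= alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$p_adj, -abs(log(out$fold_change))), ]
}

#' Two-group differential expression by ROC (AUC) classification power
#'
#' The AUC of a gene is the probability that a random group-A cell exceeds a
#' random group-B cell (ties counted half), computed from rank sums.
#' Classifier power is 2|AUC - 0.5|; a gene is called when power >= `power_min`
#' under the same detection and fold-change gates as [wilcoxon_deg()].
#'
#' @inheritParams wilcoxon_deg
#' @param power_min classification power threshold (default 0.4, i.e. AUC
#'   outside [0.3, 0.7]).
#' @return data.frame: `gene`, `auc`, `power`, `fold_change`, `frac_A`,
#'   `frac_B`, `direction`, `significant`.
#' @export
auc_deg <- function(norm, cells_A, cells_B, min_frac = 0.25, fc_min = 2,
                    power_min = 0.4) {
  if (length(cells_A) < 1 || length(cells_B) < 1)
    stop("both groups must be nonempty")
  a <- norm[, cells_A, drop = FALSE]
  b <- norm[, cells_B, drop = FALSE]
  nA <- length(cells_A)
  nB <- length(cells_B)
  frac_A <- rowMeans(a > 0)
  frac_B <- rowMeans(b > 0)
  gate <- pmax(frac_A, frac_B) >= min_frac
  genes <- rownames(norm)[gate]
  auc <- vapply(genes, function(g) {
    r <- rank(c(a[g, ], b[g, ]))
    (sum(r[seq_len(nA)]) - nA * (nA + 1) / 2) / (nA * nB)
  }, numeric(1))
  mean_A <- rowMeans(2^a[genes, , drop = FALSE] - 1)
  mean_B <- rowMeans(2^b[genes, , drop = FALSE] - 1)
  fold_change <- (mean_A + 0.01) / (mean_B + 0.01)
  power <- 2 * abs(auc - 0.5)
  out <- data.frame(
    gene = genes, auc = auc, power = power, fold_change = fold_change,
    frac_A = frac_A[gate], frac_B = frac_B[gate],
    direction = ifelse(auc >= 0.5, "up", "down"),
    significant = power >= power_min &
      (fold_change >= fc_min | fold_change <= 1 / fc_min),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(-out$power), ]
}

#' Genes overrepresented in a target cluster versus every other cluster
#'
#' A gene qualifies when it is called up-regulated in the target against each
#' listed cluster by BOTH the Wilcoxon and the ROC method (intersection over
#' comparisons and methods).
#'
#' @param norm genes x cells normalized matrix.
#' @param labels named cluster vector.
#' @param target target cluster name.
#' @param others character vector of comparison clusters.
#' @param ... thresholds passed to [wilcoxon_deg()] and [auc_deg()].
#' @return character vector of overrepresented genes.
#' @export
find_overrepresented <- function(norm, labels, target, others, ...) {
  labels <- labels[colnames(norm)]
  tcells <- names(labels)[labels == target]
  if (length(tcells) == 0) stop("target cluster absent")
  result <- NULL
  for (o in others) {
    ocells <- names(labels)[labels == o]
    if (length(ocells) == 0) stop("comparison cluster absent: ", o)
    w <- wilcoxon_deg(norm, tcells, ocells, ...)
    r <- auc_deg(norm, tcells, ocells, ...)
    up <- intersect(w$gene[w$significant & w$direction == "up"],
                    r$gene[r$significant & r$direction == "up"])
    result <- if (is.null(result)) up else intersect(result, up)
    if (length(result) == 0) break
  }
  sort(result %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-stage screen of signature-gene candidates
#'
#' From overrepresented candidates, drops (1) members of the EMP exclusion
#' list, (2) genes not highly expressed in the target cluster (per-cluster
#' median log-normalized expression < `lo` in the target), (3) genes highly
#' expressed everywhere (median > `hi` in every cluster). Each drop records
#' its reason; the surviving genes form the signature.
#'
#' @param candidates candidate gene vector (must be rows of `norm`).
#' @param norm genes x cells normalized matrix.
#' @param labels named cluster vector.
#' @param target target cluster (default "HEC").
#' @param exclusion EMP exclusion list (default the bundled 4-gene list).
#' @param lo,hi expression filters (defaults 2 and 2).
#' @return list (SignatureResult): `stages` (named list of nested gene sets),
#'   `signature` (final genes), `reasons` (data.frame gene/reason for drops).
#' @export
screen_signature <- function(candidates, norm, labels, target = "HEC",
                             exclusion = default_panels()$emp,
                             lo = 2, hi = 2) {
  if (!all(candidates %in% rownames(norm)))
    stop("candidates must be present in the matrix")
  if (length(candidates) == 0)
    return(list(stages = list(candidates = character(),
                              after_emp = character(),
                              after_target_expression = character(),
                              signature = character()),
                signature = character(),
                reasons = data.frame(gene = character(),
                                     reason = character())))
  labels <- labels[colnames(norm)]
  clusters <- unique(labels)
  med <- sapply(clusters, function(cl)
    apply(norm[candidates, labels == cl, drop = FALSE], 1, stats::median))
  med <- matrix(med, nrow = length(candidates),
                dimnames = list(candidates, clusters))
  reasons <- data.frame(gene = character(), reason = character(),
                        stringsAsFactors = FALSE)
  s1 <- setdiff(candidates, exclusion)
  emp_hit <- intersect(candidates, exclusion)
  if (length(emp_hit))
    reasons <- rbind(reasons, data.frame(gene = emp_hit,
                                         reason = "EMP exclusion"))
  low <- s1[med[s1, target] < lo]
  s2 <- setdiff(s1, low)
  if (length(low))
    reasons <- rbind(reasons, data.frame(gene = low,
                                         reason = "not highly expressed in target"))
  ubiq <- s2[rowSums(med[s2, , drop = FALSE] > hi) == length(clusters)]
  s3 <- setdiff(s2, ubiq)
  if (length(ubiq))
    reasons <- rbind(reasons, data.frame(gene = ubiq,
                                         reason = "highly expressed in every cluster"))
  list(stages = list(candidates = candidates, after_emp = s1,
                     after_target_expression = s2, signature = s3),
       signature = s3, reasons = reasons)
}

#' Rank genes by Pearson correlation with a reference gene
#'
#' @param norm genes x cells normalized matrix.
#' @param cells cells to correlate across.
#' @param ref_gene reference gene (must be expressed in >= 3 of the cells and
#'   non-constant).
#' @return data.frame `gene`, `r`, sorted by decreasing correlation.
#' @export
correlate_with_reference <- function(norm, cells, ref_gene) {
  x <- norm[, cells, drop = FALSE]
  if (!ref_gene %in% rownames(x)) stop("reference gene absent")
  ref <- x[ref_gene, ]
  if (sum(ref > 0) < 3) stop("reference gene expressed in fewer than 3 cells")
  if (sd(ref) == 0) stop("reference gene is constant across the cells")
  r <- apply(x, 1, function(g) suppressWarnings(cor(g, ref)))
  out <- data.frame(gene = rownames(x), r = r, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$r), ]
}

#' Flag genes as transcription factors and/or surface molecules
#'
#' @param genes gene vector.
#' @param tf_list transcription-factor gene list.
#' @param surfaceome_list surface-protein gene list.
#' @return data.frame `gene`, `is_tf`, `is_surface`.
#' @export
annotate_genes <- function(genes, tf_list, surfaceome_list) {
  data.frame(gene = genes, is_tf = genes %in% tf_list,
             is_surface = genes %in% surfaceome_list,
             row.names = NULL, stringsAsFactors = FALSE)
}
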