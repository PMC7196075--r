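#' Scale a vector of per-cell expression values to the 0-10 range
#'
#' Affine map sending the minimum to 0 and the maximum to 10; a constant
#' vector maps to all zeros.
#'
#' @param x numeric vector (one gene across cells).
#' @return scaled vector in [0, 10].
#' @export
scale_gene_0_10 <- function(x) {
  if (length(x) < 1) stop("need at least one cell")
  rng <- max(x) - min(x)
  if (rng == 0) return(rep(0, length(x)))
  (x - min(x)) / rng * 10
}

#' Bipolar arteriovenous feature scores
#'
#' Three steps: each marker gene's log-normalized expression is scaled to
#' 0-10 across all cells; each cell's scaled values are averaged within the
#' arterial panel and within the venous panel; the two per-cell averages are
#' each rescaled to 0-10 across cells. Scores of 5 serve as the
#' classification threshold.
#'
#' @param norm genes x cells normalized matrix.
#' @param arterial,venous marker panels (defaults: the 10-gene arterial and
#'   3-gene venous panels).
#' @return data.frame with `cell`, `arterial_score`, `venous_score`.
#' @export
arteriovenous_score <- function(norm,
                                arterial = default_panels()$arterial,
                                venous = default_panels()$venous) {
  score_panel <- function(panel) {
    present <- intersect(panel, rownames(norm))
    if (length(present) == 0) stop("all panel genes missing from the matrix")
    if (length(present) < length(panel))
      warning("missing panel genes: ",
              paste(setdiff(panel, present), collapse = ", "))
    scaled <- t(apply(norm[present, , drop = FALSE], 1, scale_gene_0_10))
    scale_gene_0_10(colMeans(scaled))
  }
  data.frame(cell = colnames(norm),
             arterial_score = score_panel(arterial),
             venous_score = score_panel(venous),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify arteriovenous identity from the bipolar scores
#'
#' Arterial iff arterial score > threshold and venous score <= threshold;
#' symmetric for venous; otherwise "both" or "neither".
#'
#' @param scores data.frame from [arteriovenous_score()].
#' @param threshold classification threshold (default 5).
#' @return the data.frame with an `av_class` column.
#' @export
classify_av <- function(scores, threshold = 5) {
  a <- scores$arterial_score > threshold
  v <- scores$venous_score > threshold
  scores$av_class <- ifelse(a & !v, "arterial",
                     ifelse(v & !a, "venous",
                     ifelse(a & v, "both", "neither")))
  scores
}

#' Gaussian confidence ellipse of a 2-d point cloud
#'
#' Fits a bivariate normal and returns the ellipse at the stated coverage
#' (chi-square quantile with 2 degrees of freedom).
#'
#' @param points 2-column matrix of coordinates (>= 3 non-collinear points).
#' @param level coverage level (default 0.5).
#' @return list with `center`, `radii` (semi-axes), `angle` (radians of the
#'   major axis), `cov`, `level`.
#' @export
confidence_ellipse <- function(points, level = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least three points")
  s <- stats::cov(points)
  e <- eigen(s, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values, 1e-300))
    stop("degenerate (collinear) point cloud")
  q <- stats::qchisq(level, df = 2)
  list(center = colMeans(points),
       radii = sqrt(e$values * q),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = s, level = level)
}

#' Cell-cycle program scores
#'
#' The G1/S and G2/M scores of a cell are the mean log-normalized expression
#' of the respective gene sets (43 and 54 core genes by default).
#'
#' @param norm genes x cells normalized matrix.
#' @param g1s,g2m gene sets.
#' @return data.frame with `cell`, `g1s_score`, `g2m_score`, `phase`.
#' @export
cell_cycle_scores <- function(norm, g1s = default_panels()$g1s,
                              g2m = default_panels()$g2m) {
  set_score <- function(set) {
    present <- intersect(set, rownames(norm))
    if (length(present) == 0) stop("cell-cycle gene set missing from matrix")
    colMeans(norm[present, , drop = FALSE])
  }
  s1 <- set_score(g1s)
  s2 <- set_score(g2m)
  data.frame(cell = colnames(norm), g1s_score = s1, g2m_score = s2,
             phase = assign_phase(s1, s2), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rule-based cell-cycle phase assignment
#'
#' Cells with both scores below 2 are quiescent; otherwise proliferative.
#' Among proliferative cells, G2/M score > G1/S score gives "G2M"; G1/S
#' score > G2/M score gives "G1" when the G2/M score is below 2 and "S"
#' otherwise. Exactly tied proliferative scores are assigned "G2M" (a
#' deterministic completion of the rule).
#'
#' @param g1s_score,g2m_score numeric score vectors.
#' @param threshold quiescence threshold (default 2).
#' @return character vector over {"quiescent", "G1", "S", "G2M"}.
#' @export
assign_phase <- function(g1s_score, g2m_score, threshold = 2) {
  stopifnot(length(g1s_score) == length(g2m_score),
            all(is.finite(g1s_score)), all(is.finite(g2m_score)))
  ifelse(g1s_score < threshold & g2m_score < threshold, "quiescent",
  ifelse(g2m_score >= g1s_score, "G2M",
  ifelse(g2m_score < threshold, "G1", "S")))
}
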