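#' Quality-filter cells on detected genes and total transcripts
#'
#' A cell is retained iff it has strictly more than `min_genes` detected
#' genes and strictly more than `min_umis` total UMIs, the thresholds applied
#' to the embryo dataset (2000 genes, 100,000 transcripts).
#'
#' @param counts genes x cells UMI count matrix (sparse or dense).
#' @param min_genes,min_umis strict lower thresholds.
#' @return list with `kept` (cell names), `stats` (per-cell data.frame:
#'   `cell`, `n_genes`, `n_umis`, `kept`).
#' @export
filter_cells <- function(counts, min_genes = 2000, min_umis = 1e5) {
  if (length(counts) == 0 || nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty count matrix")
  n_genes <- Matrix::colSums(counts > 0)
  n_umis <- Matrix::colSums(counts)
  kept <- n_genes > min_genes & n_umis > min_umis
  stats <- data.frame(cell = colnames(counts), n_genes = n_genes,
                      n_umis = n_umis, kept = kept, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(kept = colnames(counts)[kept], stats = stats)
}

#' Keep genes expressed in at least `min_cells` cells
#'
#' @param counts genes x cells count matrix.
#' @param min_cells minimum number of cells with nonzero counts (default 3).
#' @return character vector of retained gene names.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  n_cells <- Matrix::rowSums(counts > 0)
  rownames(counts)[n_cells >= min_cells]
}

#' Normalize UMI counts to log2(TPM/10 + 1)
#'
#' TPM here is UMIs-per-gene scaled to a per-cell total of one million; the
#' division by 10 reflects that per-cell molecule totals are mostly below a
#' million, so a transcript should not be counted several times.
#'
#' @param counts genes x cells count matrix with positive column totals.
#' @return dense genes x cells matrix of log2(TPM/10 + 1) values.
#' @export
normalize_tpm_log <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("cells with zero total counts must be filtered before normalization")
  tpm <- sweep(as.matrix(counts), 2, totals, "/") * 1e6
  log2(tpm / 10 + 1)
}

#' Remove the negative cluster and hematopoietic-marker-positive cells
#'
#' Drops every cell labelled with the negative cluster and every cell whose
#' normalized Ptprc or Spn expression exceeds 1 (strictly), the rule used to
#' purge hematopoietic contaminants before endothelial analyses.
#'
#' @param norm genes x cells normalized matrix; must contain the marker rows.
#' @param labels named cluster vector covering all columns of `norm`.
#' @param negative_cluster name of the negative cluster (default "Neg").
#' @param markers hematopoietic marker genes (default Ptprc, Spn).
#' @param threshold strict expression threshold (default 1).
#' @return character vector of retained cell names.
#' @export
exclude_hematopoietic_cells <- function(norm, labels,
                                        negative_cluster = "Neg",
                                        markers = c("Ptprc", "Spn"),
                                        threshold = 1) {
  if (!all(colnames(norm) %in% names(labels)))
    stop("labels must cover every cell")
  missing <- setdiff(markers, rownames(norm))
  if (length(missing))
    stop("marker genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  in_neg <- labels[colnames(norm)] == negative_cluster
  marker_hi <- Matrix::colSums(norm[markers, , drop = FALSE] > threshold) > 0
  colnames(norm)[!in_neg & !marker_hi]
}

#' Run the full QC + normalization stage
#'
#' Applies [filter_cells()], then [filter_genes()] on the retained cells,
#' then [normalize_tpm_log()].
#'
#' @param counts genes x cells count matrix.
#' @param min_genes,min_umis,min_cells stage thresholds.
#' @return list with `norm`, `counts` (filtered), `cell_stats`, `kept_cells`,
#'   `kept_genes`.
#' @export
qc_normalize <- function(counts, min_genes = 2000, min_umis = 1e5,
                         min_cells = 3) {
  fc <- filter_cells(counts, min_genes, min_umis)
  sub <- counts[, fc$kept, drop = FALSE]
  genes <- filter_genes(sub, min_cells)
  sub <- sub[genes, , drop = FALSE]
  list(norm = normalize_tpm_log(sub), counts = sub, cell_stats = fc$stats,
       kept_cells = fc$kept, kept_genes = genes)
}
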