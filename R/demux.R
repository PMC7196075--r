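#' Parse the STRT read structure of a set of read pairs
#'
#' The primer read must begin with the fixed anchor; the 8 nt after the
#' anchor are the sample barcode and the following 8 nt the UMI. The cDNA
#' read is trimmed of its template-switch-oligo (TSO) prefix and of a
#' trailing polyA run (>= 10 bases, allowing one mismatch). Pairs whose
#' primer read lacks the anchor are flagged unparseable, not dropped with an
#' error: their barcode/UMI come back NA.
#'
#' @param pairs data.frame as returned by [read_fastq_pair()] (`seq1` = cDNA
#'   read, `seq2` = primer read).
#' @param anchor fixed anchor sequence preceding the barcode.
#' @param tso TSO prefix to strip from the cDNA read.
#' @return data.frame with `id`, `barcode`, `umi`, `cdna`, `parseable`.
#' @export
parse_read_structure <- function(pairs, anchor = STRT_ANCHOR,
                                 tso = STRT_TSO) {
  ok <- startsWith(pairs$seq2, anchor)
  off <- nchar(anchor)
  barcode <- ifelse(ok, substr(pairs$seq2, off + 1L, off + BARCODE_LENGTH),
                    NA_character_)
  umi <- ifelse(ok, substr(pairs$seq2, off + BARCODE_LENGTH + 1L,
                           off + BARCODE_LENGTH + UMI_LENGTH), NA_character_)
  cdna <- pairs$seq1
  has_tso <- startsWith(cdna, tso)
  cdna[has_tso] <- substr(cdna[has_tso], nchar(tso) + 1L, nchar(cdna[has_tso]))
  cdna <- trim_polya(cdna)
  data.frame(id = pairs$id, barcode = barcode, umi = umi, cdna = cdna,
             parseable = ok, stringsAsFactors = FALSE)
}

# Remove a trailing polyA run of length >= min_run, allowing one interior
# mismatch: if the base immediately before the trailing A run is itself
# preceded by more A's, the whole A..X..A suffix counts as one run. The
# mismatch must be interior (A's on both sides), so a clean non-A base at
# the end of the cDNA is never trimmed.
trim_polya <- function(seqs, min_run = 10L) {
  n <- nchar(seqs)
  ta <- n - nchar(sub("A*$", "", seqs))
  has_mm <- ta < n & ta >= 1L
  pre <- ifelse(has_mm, substr(seqs, 1L, n - ta - 1L), "")
  tb <- nchar(pre) - nchar(sub("A*$", "", pre))
  len_mm <- ta + 1L + tb
  trim <- ifelse(has_mm & tb > 0L & len_mm >= min_run, len_mm,
                 ifelse(ta >= min_run, ta, 0L))
  substr(seqs, 1L, n - trim)
}

#' Filter read pairs on adapter contamination and N content
#'
#' A pair is rejected when its cDNA read contains the adapter sequence or
#' when the fraction of N bases in the cDNA read exceeds 0.10 (strictly).
#'
#' @param pairs data.frame from [read_fastq_pair()].
#' @param adapter adapter sequence to search for (fixed match).
#' @param max_n_frac maximum tolerated N fraction (default 0.10).
#' @return list with `kept` (filtered data.frame) and `tally` (named counts:
#'   `input`, `adapter`, `high_n`, `kept`).
#' @export
filter_reads <- function(pairs, adapter = DEFAULT_ADAPTER, max_n_frac = 0.10) {
  has_adapter <- grepl(adapter, pairs$seq1, fixed = TRUE)
  n_frac <- nchar(gsub("[^N]", "", pairs$seq1)) / nchar(pairs$seq1)
  high_n <- n_frac > max_n_frac
  drop <- has_adapter | high_n
  list(
    kept = pairs[!drop, , drop = FALSE],
    tally = c(input = nrow(pairs), adapter = sum(has_adapter),
              high_n = sum(high_n & !has_adapter), kept = sum(!drop))
  )
}

#' Demultiplex parsed reads by exact sample barcode
#'
#' @param parsed data.frame from [parse_read_structure()].
#' @param barcode_map named character vector, cell name -> 8-nt barcode.
#' @return list with `reads` (parsed rows annotated with `cell`; unmatched
#'   and unparseable rows removed) and `tally` (`matched`, `unmatched`,
#'   `unparseable`, plus per-cell read counts in `per_cell`).
#' @export
demultiplex <- function(parsed, barcode_map) {
  if (anyDuplicated(barcode_map)) stop("barcode map has collisions")
  if (any(nchar(barcode_map) != BARCODE_LENGTH))
    stop("barcodes must be 8 nt over ACGT")
  lut <- stats::setNames(names(barcode_map), barcode_map)
  cell <- lut[parsed$barcode]
  unparseable <- !parsed$parseable
  unmatched <- parsed$parseable & is.na(cell)
  keep <- !is.na(cell) & parsed$parseable
  reads <- parsed[keep, , drop = FALSE]
  reads$cell <- cell[keep]
  per_cell <- table(factor(reads$cell, levels = names(barcode_map)))
  list(reads = reads,
       tally = list(matched = sum(keep), unmatched = sum(unmatched),
                    unparseable = sum(unparseable),
                    per_cell = as.integer(per_cell) |>
                      stats::setNames(names(barcode_map))))
}

#' Assign genes to demultiplexed reads by exact tag lookup
#'
#' Synthetic reads encode gene identity as a fixed-length tag at the start of
#' the trimmed cDNA (alignment is out of scope). Reads whose tag matches no
#' known gene get NA.
#'
#' @param reads data.frame from [demultiplex()].
#' @param tag_map named tag vector from [gene_tags()].
#' @return the reads with a `gene` column.
#' @export
assign_genes <- function(reads, tag_map) {
  lut <- stats::setNames(names(tag_map), tag_map)
  tag <- substr(reads$cdna, 1L, GENE_TAG_LENGTH)
  reads$gene <- unname(lut[tag])
  reads
}

#' Deduplicate reads into a UMI count matrix
#'
#' The count of a gene in a cell is the number of distinct UMI sequences
#' among that gene's reads in that cell. Mitochondrial genes ("mt-" prefix)
#' are excluded from the matrix. Reads without a gene assignment are ignored
#' (tallied).
#'
#' @param reads data.frame with `cell`, `gene`, `umi` columns.
#' @param genes gene universe for the matrix rows (default: genes observed).
#' @param cells cell universe for the columns (default: cells observed).
#' @return list with `counts` (sparse genes x cells dgCMatrix, mt- excluded),
#'   `molecules` (data.frame cell/gene/umi/reads, one row per distinct
#'   molecule) and `n_unassigned`.
#' @export
dedup_count <- function(reads, genes = NULL, cells = NULL) {
  n_unassigned <- sum(is.na(reads$gene))
  reads <- reads[!is.na(reads$gene), , drop = FALSE]
  key <- paste(reads$cell, reads$gene, reads$umi, sep = "\r")
  mult <- table(key)
  first <- !duplicated(key)
  molecules <- data.frame(
    cell = reads$cell[first], gene = reads$gene[first],
    umi = reads$umi[first],
    reads = as.integer(mult[key[first]]),
    stringsAsFactors = FALSE
  )
  if (is.null(genes)) genes <- sort(unique(molecules$gene))
  if (is.null(cells)) cells <- sort(unique(molecules$cell))
  keep <- !startsWith(genes, "mt-")
  genes <- genes[keep]
  inmat <- molecules$gene %in% genes & molecules$cell %in% cells
  m <- molecules[inmat, , drop = FALSE]
  counts <- Matrix::sparseMatrix(
    i = match(m$gene, genes), j = match(m$cell, cells), x = 1,
    dims = c(length(genes), length(cells)), dimnames = list(genes, cells)
  )
  counts <- methods::as(counts, "CsparseMatrix")
  list(counts = counts, molecules = molecules, n_unassigned = n_unassigned)
}

#' Quantify a paired STRT FASTQ run into a deduplicated count matrix
#'
#' Convenience wrapper chaining [read_fastq_pair()], [filter_reads()],
#' [parse_read_structure()], [demultiplex()], [assign_genes()] and
#' [dedup_count()], with a conservation check that every input read is
#' accounted for exactly once (kept, rejected, unparseable or unmatched).
#'
#' @param fastq1,fastq2 paths to the cDNA and primer read files.
#' @param barcode_map named barcode vector (cell -> barcode).
#' @param tag_map named gene tag vector ([gene_tags()]).
#' @param adapter adapter for contamination filtering.
#' @return list with `counts`, `molecules`, and `qc` (a named tally).
#' @export
count_fastq_run <- function(fastq1, fastq2, barcode_map, tag_map,
                            adapter = DEFAULT_ADAPTER) {
  pairs <- read_fastq_pair(fastq1, fastq2)
  filt <- filter_reads(pairs, adapter = adapter)
  parsed <- parse_read_structure(filt$kept)
  dm <- demultiplex(parsed, barcode_map)
  reads <- assign_genes(dm$reads, tag_map)
  dd <- dedup_count(reads, genes = names(tag_map), cells = names(barcode_map))
  qc <- c(
    input = unname(filt$tally["input"]),
    adapter = unname(filt$tally["adapter"]),
    high_n = unname(filt$tally["high_n"]),
    unparseable = dm$tally$unparseable,
    unmatched = dm$tally$unmatched,
    unassigned_gene = dd$n_unassigned,
    counted_reads = dm$tally$matched - dd$n_unassigned
  )
  stopifnot(qc["input"] == qc["adapter"] + qc["high_n"] + qc["unparseable"] +
              qc["unmatched"] + qc["unassigned_gene"] + qc["counted_reads"])
  list(counts = dd$counts, molecules = dd$molecules, qc = qc)
}
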