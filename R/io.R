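#' Read a pair of (optionally gzipped) FASTQ files
#'
#' Loads matched paired-end records into a data frame. Record order must agree
#' between the two files (standard Illumina pairing); ids are taken from read 1
#' with any `/1`, `/2` or space-separated suffix removed.
#'
#' @param fastq1 path to the cDNA read file (read 1).
#' @param fastq2 path to the barcode/UMI read file (read 2).
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) {
    stop("paired FASTQ files have different record counts")
  }
  data.frame(
    id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual,
    stringsAsFactors = FALSE
  )
}

read_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(lines), by = 4L)
  id <- sub("^@", "", lines[idx])
  id <- sub("[/ ].*$", "", id)
  seq <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence/quality length mismatch in ", path)
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# Write 4-line FASTQ records gzip-compressed. R's gzip connection writes a
# zero mtime header, so a fixed seed yields byte-identical files across runs.
write_fastq_gz <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  con <- gzfile(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("@", id, "\n", seq, "\n+\n", qual, "\n"), con, sep = "")
  invisible(path)
}

#' Write a UMI count matrix as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir`, the layout
#' used by common single-cell toolkits.
#'
#' @param counts sparse or dense genes x cells matrix with dimnames.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a UMI count matrix written by [write_count_matrix()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return a sparse dgCMatrix, genes x cells.
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Read a one-gene-per-line panel file
#'
#' Blank lines and `#` comments are ignored.
#'
#' @param path text file, one gene symbol per line.
#' @return character vector of gene symbols.
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Default gene panels shipped with the package
#'
#' Returns the bundled marker panels: 10 arterial and 3 venous endothelial
#' markers, the 43-gene G1/S and 54-gene G2/M cell-cycle core sets (the
#' Tirosh core sets in mouse nomenclature), the default cell-cycle exclusion
#' list (union of the two core sets, standing in for the GO:0007049 term
#' members), and the 4-gene erythro-myeloid progenitor (EMP) exclusion list.
#'
#' @return named list of character vectors: `arterial`, `venous`, `g1s`,
#'   `g2m`, `cc_exclude`, `emp`.
#' @export
default_panels <- function() {
  p <- function(f) read_panel(system.file("extdata", f, package = "hecscreen",
                                          mustWork = TRUE))
  g1s <- p("g1s_genes.txt")
  g2m <- p("g2m_genes.txt")
  list(
    arterial = p("arterial_markers.txt"),
    venous = p("venous_markers.txt"),
    g1s = g1s,
    g2m = g2m,
    cc_exclude = union(g1s, g2m),
    emp = p("emp_exclusion.txt")
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
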