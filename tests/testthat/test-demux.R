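make_pair <- function(seq1, seq2, id = sprintf("r%03d", seq_along(seq1))) {
  data.frame(id = id, seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
             seq2 = seq2, qual2 = strrep("I", nchar(seq2)),
             stringsAsFactors = FALSE)
}

anchor <- hecscreen:::STRT_ANCHOR
tso <- hecscreen:::STRT_TSO

test_that("read structure parsing recovers barcode, UMI and trimmed cDNA", {
  p <- make_pair(
    seq1 = paste0(tso, "CGTCGTCGTCGTCGTCGTCG", strrep("A", 25)),
    seq2 = paste0(anchor, "ACGTACGT", "TTTTAAAA", strrep("T", 25))
  )
  out <- parse_read_structure(p)
  expect_equal(out$barcode, "ACGTACGT")
  expect_equal(out$umi, "TTTTAAAA")
  expect_equal(out$cdna, "CGTCGTCGTCGTCGTCGTCG")
  expect_true(out$parseable)
})

test_that("reads without the anchor are flagged unparseable, not fatal", {
  p <- make_pair(seq1 = "CCCCGGGG", seq2 = paste0("GGGG", "ACGTACGT"))
  out <- parse_read_structure(p)
  expect_false(out$parseable)
  expect_true(is.na(out$barcode))
})

test_that("polyA trimming removes runs of >= 10 A allowing one interior mismatch", {
  # no polyA run: unchanged after TSO trim
  expect_equal(hecscreen:::trim_polya("CGTCGTCGTAAAA"), "CGTCGTCGTAAAA")
  # exact run of 10+
  expect_equal(hecscreen:::trim_polya(paste0("CGTCG", strrep("A", 12))), "CGTCG")
  # one interior mismatch inside a long run
  expect_equal(hecscreen:::trim_polya(paste0("CGT", "AAAAA", "G", "AAAAAA")),
               "CGT")
  # interior mismatch but total below 10: only an exact >= 10 suffix counts
  expect_equal(hecscreen:::trim_polya("CGTAAAGAAAA"), "CGTAAAGAAAA")
  # a clean non-A base at the end is never trimmed
  expect_equal(hecscreen:::trim_polya(paste0("CG", strrep("A", 11), "T")),
               paste0("CG", strrep("A", 11), "T"))
})

test_that("read filter enforces adapter and strict 10% N rules", {
  n100 <- function(k) paste0(strrep("N", k), strrep("G", 100 - k))
  p <- make_pair(
    seq1 = c(n100(11), n100(10), paste0("GG", hecscreen:::DEFAULT_ADAPTER, "GG")),
    seq2 = rep(paste0(anchor, "ACGTACGT", "AAAATTTT", strrep("T", 25)), 3)
  )
  out <- filter_reads(p)
  expect_equal(out$kept$seq1, n100(10))  # exactly 10% N is kept
  expect_equal(unname(out$tally[c("adapter", "high_n")]), c(1, 1))
})

test_that("demultiplexing is exact-match with unmatched tally", {
  map <- c(cellA = "ACGTACGT", cellB = "TTTTCCCC")
  p <- make_pair(
    seq1 = rep("CGTCGTCGT", 3),
    seq2 = c(paste0(anchor, "ACGTACGT", "AAAATTTT", strrep("T", 25)),
             paste0(anchor, "ACGTACGA", "AAAATTTT", strrep("T", 25)),  # 1 edit
             paste0(anchor, "TTTTCCCC", "GGGGTTTT", strrep("T", 25)))
  )
  parsed <- parse_read_structure(p)
  dm <- demultiplex(parsed, map)
  expect_equal(dm$tally$matched, 2)
  expect_equal(dm$tally$unmatched, 1)
  expect_equal(sort(dm$reads$cell), c("cellA", "cellB"))
})

test_that("UMI deduplication counts distinct UMIs and excludes mt- genes", {
  reads <- data.frame(
    cell = c(rep("c1", 7), "c1", "c1", "c1", "c2"),
    gene = c(rep("Gapdh", 7), rep("Actb", 3), "mt-Co1"),
    umi = c(rep("AAAACCCC", 7), "AAAACCCC", "CCCCGGGG", "GGGGTTTT", "TTTTAAAA"),
    stringsAsFactors = FALSE
  )
  dd <- dedup_count(reads, genes = c("Actb", "Gapdh", "mt-Co1"),
                    cells = c("c1", "c2"))
  expect_equal(unname(dd$counts["Gapdh", "c1"]), 1)  # 7 copies, 1 molecule
  expect_equal(unname(dd$counts["Actb", "c1"]), 3)   # 3 distinct UMIs
  expect_false("mt-Co1" %in% rownames(dd$counts))
  # dedup is idempotent and invariant to read order and duplication
  set.seed(4)
  perm <- reads[sample.int(nrow(reads)), ]
  dd2 <- dedup_count(rbind(perm, perm), genes = c("Actb", "Gapdh", "mt-Co1"),
                     cells = c("c1", "c2"))
  expect_identical(as.matrix(dd$counts), as.matrix(dd2$counts))
})

test_that("full FASTQ quantification conserves reads and matches truth", {
  fx <- small_tracked_sim()
  f1 <- tempfile(fileext = ".fq.gz"); f2 <- tempfile(fileext = ".fq.gz")
  cfg <- fx$cfg
  cfg$frac_adapter <- 0.02
  cfg$frac_n <- 0.03
  spikes <- simulate_fastq(fx$sim$truth, cfg, fastq1 = f1, fastq2 = f2)
  res <- count_fastq_run(f1, f2, fx$sim$truth$barcodes,
                         gene_tags(fx$sim$truth$gene_table$gene))
  # conservation: every input read accounted for exactly once
  expect_equal(unname(res$qc["input"]), nrow(spikes))
  expect_equal(unname(res$qc["input"]),
               unname(sum(res$qc[c("adapter", "high_n", "unparseable",
                                   "unmatched", "unassigned_gene",
                                   "counted_reads")])))
  # all and only the spiked junk reads are removed by the QC filters
  expect_equal(unname(res$qc["adapter"]), sum(spikes$spike == "adapter"))
  expect_equal(unname(res$qc["high_n"]), sum(spikes$spike == "nrich"))
  # the deduplicated matrix equals the simulated ground truth
  m <- as.matrix(res$counts[rownames(fx$sim$counts), colnames(fx$sim$counts)])
  expect_equal(unname(m), unname(as.matrix(fx$sim$counts)))
})
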