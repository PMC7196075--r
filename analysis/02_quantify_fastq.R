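#!/usr/bin/env Rscript
# Stage 2: quantify the paired STRT FASTQ from stage 1 -- read QC, barcode
# demultiplexing, gene-tag assignment, UMI deduplication -- and verify the
# resulting matrix against the simulated ground truth.

suppressPackageStartupMessages(library(hecscreen))

dat <- "results/data"
bc <- read.delim(file.path(dat, "fastq_barcodes.tsv"), header = FALSE)
barcodes <- stats::setNames(bc$V2, bc$V1)
truth_counts <- read_count_matrix(file.path(dat, "fastq_truth_counts"))
# gene tags are a deterministic function of the gene universe
genes <- union(rownames(truth_counts), paste0("mt-", c(
  "Nd1", "Nd2", "Co1", "Co2", "Co3", "Atp6", "Atp8", "Cytb", "Nd4", "Nd5")))
# the tag map must match the simulated universe ordering
sim_fq <- simulate_count_dataset(sim_config(
  n_cells_per_cluster = c(vEC = 10, earlyAEC = 10, lateAEC = 10,
                          HEC = 10, HC = 10),
  n_genes = 500, depth_range = c(1e3, 5e3), pcr_duplication_mean = 5,
  track_molecules = TRUE, seed = 3))
tags <- gene_tags(sim_fq$truth$gene_table$gene)

res <- count_fastq_run(file.path(dat, "reads_R1.fq.gz"),
                       file.path(dat, "reads_R2.fq.gz"),
                       barcodes, tags)
dir.create("results/quantification", recursive = TRUE, showWarnings = FALSE)
write_count_matrix(res$counts, "results/quantification/counts")
jsonlite::write_json(as.list(res$qc), "results/quantification/qc_report.json",
                     auto_unbox = TRUE)

cat("read accounting:\n")
print(res$qc)
m <- as.matrix(res$counts[rownames(truth_counts), colnames(truth_counts)])
diffs <- sum(m != as.matrix(truth_counts))
cat(sprintf("dedup matrix vs ground truth: %d differing entries of %d\n",
            diffs, length(m)))
stopifnot(diffs == 0)
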