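#!/usr/bin/env Rscript
# Stage 3: cell and gene quality filters (>2000 genes, >100,000 transcripts;
# genes in >= 3 cells) and log2(TPM/10 + 1) normalization of the reference
# dataset.

suppressPackageStartupMessages(library(hecscreen))

counts <- read_count_matrix("results/data/counts")
qc <- qc_normalize(counts)
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.csv(qc$cell_stats, "results/qc/cell_stats.csv", row.names = FALSE)

cat(sprintf("cells: %d of %d pass (>2000 genes and >100,000 transcripts)\n",
            length(qc$kept_cells), ncol(counts)))
cat(sprintf("genes: %d of %d expressed in >= 3 cells\n",
            length(qc$kept_genes), nrow(counts)))
cat(sprintf("mean detected genes per retained cell: %.0f (range %d - %d)\n",
            mean(qc$cell_stats$n_genes[qc$cell_stats$kept]),
            min(qc$cell_stats$n_genes[qc$cell_stats$kept]),
            max(qc$cell_stats$n_genes[qc$cell_stats$kept])))
cat(sprintf("mean transcripts per retained cell: %.0f\n",
            mean(qc$cell_stats$n_umis[qc$cell_stats$kept])))
tpm_err <- max(abs(colSums((2^qc$norm - 1) * 10) - 1e6) / 1e6)
cat(sprintf("TPM conservation: max relative error %.2e\n", tpm_err))
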