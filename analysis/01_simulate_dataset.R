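#!/usr/bin/env Rscript
# Stage 1: generate the reference synthetic embryo-like dataset (6 planted
# clusters, depths 1e5-3e6 UMIs/cell) plus a small molecule-tracked dataset
# with paired STRT FASTQ for the quantification stage. Everything is
# seed-determined; rerunning reproduces the files byte for byte.

suppressPackageStartupMessages(library(hecscreen))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42)
sim <- simulate_count_dataset(cfg)
write_count_matrix(sim$counts, file.path(out, "counts"))
write.csv(sim$metadata, file.path(out, "cell_metadata.csv"), row.names = FALSE)
jsonlite::write_json(
  list(cell_cluster = as.list(sim$truth$cell_cluster),
       planted_phase = as.list(sim$truth$planted_phase),
       planted_de = sim$truth$planted_de,
       gene_roles = sim$truth$gene_table[, c("gene", "role")]),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("reference dataset: %d genes x %d cells, %.2fM molecules\n",
            nrow(sim$counts), ncol(sim$counts),
            sum(sim$counts) / 1e6))
cat(sprintf("depth range: %d - %d UMIs/cell\n",
            min(Matrix::colSums(sim$counts)),
            max(Matrix::colSums(sim$counts))))
print(table(sim$metadata$cluster))

# small tracked dataset + FASTQ for the quantification oracle
cfg_fq <- sim_config(
  n_cells_per_cluster = c(vEC = 10, earlyAEC = 10, lateAEC = 10,
                          HEC = 10, HC = 10),
  n_genes = 500, depth_range = c(1e3, 5e3), pcr_duplication_mean = 5,
  track_molecules = TRUE, seed = 3
)
sim_fq <- simulate_count_dataset(cfg_fq)
write_count_matrix(sim_fq$counts, file.path(out, "fastq_truth_counts"))
writeLines(paste(names(sim_fq$truth$barcodes), sim_fq$truth$barcodes,
                 sep = "\t"),
           file.path(out, "fastq_barcodes.tsv"))
reads <- simulate_fastq(sim_fq$truth, cfg_fq,
                        fastq1 = file.path(out, "reads_R1.fq.gz"),
                        fastq2 = file.path(out, "reads_R2.fq.gz"))
cat(sprintf("FASTQ demo: %d molecules sequenced as %d read pairs\n",
            nrow(sim_fq$truth$molecule_table), nrow(reads)))
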