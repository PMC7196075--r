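#' Pipeline configuration
#'
#' Collects every stage parameter in one auditable object. Defaults equal the
#' thresholds the analysis is defined with: QC at >2000 genes and >100,000
#' transcripts, genes kept in >= 3 cells, HVG mean in (1, 8) and dispersion
#' > 1, 15 PCs, Ptprc/Spn exclusion at > 1, DEG fold >= 2 at adjusted
#' P <= 0.05 with detection fraction 0.25, arteriovenous threshold 5,
#' cell-cycle phase threshold 2, and signature expression filters at 2.
#'
#' @param sim a [sim_config()] describing the synthetic input dataset.
#' @param out_dir output directory.
#' @param target signature target cluster (default "HEC").
#' @param signature_others comparison clusters for the overrepresentation
#'   step (default vEC, earlyAEC, lateAEC, HC).
#' @param pattern_reference,pattern_branches reference and branch clusters of
#'   the directional pattern assignment.
#' @param min_genes,min_umis,min_cells,hvg_mean_lo,hvg_mean_hi,hvg_disp_min
#'   QC and HVG thresholds.
#' @param n_pcs,knn clustering parameters.
#' @param marker_threshold Ptprc/Spn exclusion threshold.
#' @param min_frac,fc_min,alpha,power_min DEG thresholds.
#' @param av_threshold arteriovenous classification threshold.
#' @param phase_threshold cell-cycle score threshold.
#' @param expr_lo,expr_hi signature expression filters.
#' @param seed pipeline seed (also seeds the simulation unless `sim` sets its
#'   own).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            out_dir = tempfile("hecscreen_run_"),
                            target = "HEC",
                            signature_others = c("vEC", "earlyAEC",
                                                 "lateAEC", "HC"),
                            pattern_reference = "earlyAEC",
                            pattern_branches = c("lateAEC", "HEC"),
                            min_genes = 2000, min_umis = 1e5, min_cells = 3,
                            hvg_mean_lo = 1, hvg_mean_hi = 8,
                            hvg_disp_min = 1, n_pcs = 15, knn = 20,
                            marker_threshold = 1, min_frac = 0.25,
                            fc_min = 2, alpha = 0.05, power_min = 0.4,
                            av_threshold = 5, phase_threshold = 2,
                            expr_lo = 2, expr_hi = 2, seed = 42L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in order -- simulate, qc, cluster, score, signature,
#' patterns -- writing each stage's outputs and a manifest (parameters, seed,
#' md5 of every written file) under `config$out_dir`. Reruns with the same
#' configuration reproduce identical outputs. Computed clusters are renamed
#' by their majority planted cluster so downstream stages use the canonical
#' names, the deterministic counterpart of assigning cluster identities from
#' known markers.
#'
#' @param config a [pipeline_config()].
#' @return list with the stage results and the manifest (invisibly written as
#'   JSON).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- default_panels()

  sim <- simulate_count_dataset(config$sim)
  write_count_matrix(sim$counts, file.path(config$out_dir, "counts"))
  utils::write.csv(sim$metadata,
                   file.path(config$out_dir, "cell_metadata.csv"),
                   row.names = FALSE)

  qc <- qc_normalize(sim$counts, config$min_genes, config$min_umis,
                     config$min_cells)
  utils::write.csv(qc$cell_stats, file.path(config$out_dir, "qc_cells.csv"),
                   row.names = FALSE)

  hvg <- select_hvgs(qc$norm, cc_go_genes = panels$cc_exclude,
                     mean_lo = config$hvg_mean_lo,
                     mean_hi = config$hvg_mean_hi,
                     disp_min = config$hvg_disp_min)
  emb <- pca_embed(qc$norm, hvg$genes, n_pcs = config$n_pcs)
  raw_labels <- cluster_cells(emb$scores, k = config$knn, seed = config$seed)
  negctrl <- stats::setNames(sim$metadata$negative_control,
                             sim$metadata$cell)
  raw_labels <- reclassify_negative_cluster(raw_labels, negctrl)
  labels <- rename_by_majority(raw_labels,
                               sim$truth$cell_cluster[names(raw_labels)])
  utils::write.csv(
    data.frame(cell = names(labels), cluster = unname(labels),
               raw_cluster = unname(raw_labels)),
    file.path(config$out_dir, "clusters.csv"), row.names = FALSE)

  kept <- exclude_hematopoietic_cells(qc$norm, labels,
                                      threshold = config$marker_threshold)
  norm_ec <- qc$norm[, kept, drop = FALSE]
  labels_ec <- labels[kept]

  av <- classify_av(arteriovenous_score(qc$norm, panels$arterial,
                                        panels$venous),
                    threshold = config$av_threshold)
  cc <- cell_cycle_scores(qc$norm, panels$g1s, panels$g2m)
  scores <- merge(av, cc, by = "cell", sort = TRUE)
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE)

  sig_labels <- labels
  candidates <- find_overrepresented(
    qc$norm, sig_labels, config$target, config$signature_others,
    min_frac = config$min_frac, fc_min = config$fc_min)
  screen <- screen_signature(candidates, qc$norm, sig_labels,
                             target = config$target, exclusion = panels$emp,
                             lo = config$expr_lo, hi = config$expr_hi)
  jsonlite::write_json(
    list(candidates = screen$stages$candidates,
         signature = screen$signature, reasons = screen$reasons),
    file.path(config$out_dir, "signature.json"), auto_unbox = FALSE,
    pretty = TRUE)

  pat_clusters <- c(config$pattern_reference, config$pattern_branches)
  pat_cells <- names(labels_ec)[labels_ec %in% pat_clusters]
  deg <- anova_tukey_deg(norm_ec[, pat_cells, drop = FALSE],
                         labels_ec[pat_cells],
                         alpha = config$alpha, fc = config$fc_min)
  patterns <- assign_directional_patterns(
    deg$pairwise[deg$pairwise$gene %in% deg$genes, , drop = FALSE],
    config$pattern_reference, config$pattern_branches[1],
    config$pattern_branches[2])
  utils::write.csv(patterns, file.path(config$out_dir, "patterns.csv"),
                   row.names = FALSE)

  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hecscreen")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    sim_parameters = unclass(config$sim),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(sim = sim, qc = qc, hvg = hvg, embedding = emb,
                 labels = labels, kept_cells = kept, scores = scores,
                 candidates = candidates, screen = screen, deg = deg,
                 patterns = patterns, manifest = manifest))
}

# Rename computed clusters by the majority planted cluster among their
# members; the Neg label assigned by reclassification is kept.
rename_by_majority <- function(labels, truth) {
  out <- labels
  for (cl in setdiff(unique(labels), "Neg")) {
    members <- names(labels)[labels == cl]
    tab <- sort(table(truth[members]), decreasing = TRUE)
    out[members] <- names(tab)[1]
  }
  out
}
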