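#' @importFrom stats rgamma rmultinom rpois runif rnorm cor sd var
#' @importFrom utils head
NULL

# Fixed sequences of the STRT-style read layout used throughout:
# the primer read is  <anchor><8-nt sample barcode><8-nt UMI><T25>,
# the cDNA read is    <TSO><gene tag><polyA>.
STRT_ANCHOR <- "TCAGACGTGTGCTCTTCCGATCT"
STRT_TSO <- "AAGCAGTGGTATCAACGCAGAGTACATGGG"
DEFAULT_ADAPTER <- "AGATCGGAAGAGC"

UMI_LENGTH <- 8L
BARCODE_LENGTH <- 8L
GENE_TAG_LENGTH <- 20L

#' Configuration for the synthetic STRT dataset generator
#'
#' Defines the study conditions the generator emulates: 6 planted cell
#' clusters with endothelial / arterial / venous / hematopoietic marker
#' programs, per-cell sequencing depths spanning roughly 1e5 to 3e6
#' transcripts, over-dispersed UMI counts, cluster-specific proliferative
#' fractions driving planted G1/S / S / G2/M expression programs,
#' HEC-exclusive signature genes, EMP-like confounders, ubiquitously high
#' genes, and hematopoietic contaminants expressing Ptprc/Spn.
#'
#' @param n_cells_per_cluster named integer vector, cells per cluster. The
#'   canonical cluster names (vEC, earlyAEC, lateAEC, pEC, pAEC, HEC, HC,
#'   Neg) carry predefined marker programs; other names get baseline-only
#'   cells (useful for null datasets).
#' @param n_genes total genes in the universe, including the special panels.
#' @param depth_range per-cell total UMI bounds; depths are drawn
#'   log-uniformly within them.
#' @param nb_dispersion over-dispersion of counts (gamma-multinomial, so the
#'   marginal per-gene variance is approximately negative-binomial with
#'   var = mu + nb_dispersion * mu^2).
#' @param marker_effect fold elevation of planted marker programs (>= 1;
#'   1 plants no signal).
#' @param proliferative_fraction named vector, fraction of cycling cells per
#'   cluster; clusters not named get 0.
#' @param planted_signature_genes genes elevated only in HEC.
#' @param planted_emp_genes EMP-list genes, also elevated only in HEC (so
#'   they are differential but must be excluded by the signature screen).
#' @param planted_ubiquitous_genes genes highly expressed in every cluster.
#' @param planted_de optional data.frame(gene, cluster, fold) of extra
#'   gene-level plants, applied multiplicatively in the named cluster.
#' @param n_private_markers private marker genes planted per cluster (drawn
#'   from the filler pool) at `marker_effect`; they make clusters separable.
#' @param n_shallow_cells extra low-depth cells (depth 2e4--6e4) planted to
#'   fail the QC depth filter; flagged in the metadata.
#' @param mito_tpm baseline TPM of the 10 "mt-" genes (0 keeps the output
#'   matrix totals exactly equal to the drawn depths).
#' @param pcr_duplication_mean mean sequenced copies per molecule (>= 1).
#' @param seq_error_rate per-base substitution rate on the cDNA read.
#' @param frac_adapter,frac_n fractions of extra junk read pairs spiked as
#'   adapter-contaminated or N-rich.
#' @param track_molecules record the molecule-level UMI table (needed by
#'   [simulate_fastq()]; off by default because it is large at full depth).
#' @param cluster_programs optional override of the cluster -> panel program
#'   map, a named list of named numeric vectors (panel name -> fold).
#'   Referencing an unknown panel is a configuration error.
#' @param seed integer RNG seed; a fixed seed gives byte-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells_per_cluster = c(vEC = 60, earlyAEC = 80,
                                               lateAEC = 80, HEC = 60,
                                               HC = 40, Neg = 40),
                       n_genes = 3000,
                       depth_range = c(1e5, 3e6),
                       nb_dispersion = 0.4,
                       marker_effect = 20,
                       proliferative_fraction = c(vEC = 0.2, earlyAEC = 0.2,
                                                  lateAEC = 0.05, pEC = 0.3,
                                                  pAEC = 0.25, HEC = 0.8,
                                                  HC = 0.6, Neg = 0.3),
                       planted_signature_genes = sprintf("HecSig%02d", 1:11),
                       planted_emp_genes = c("Gsta4", "Spi1", "Alox5ap", "Myb"),
                       planted_ubiquitous_genes = c("Actb", "Gapdh", "Rpl13a"),
                       planted_de = NULL,
                       n_private_markers = 15,
                       n_shallow_cells = 0,
                       mito_tpm = 0,
                       pcr_duplication_mean = 5,
                       seq_error_rate = 0,
                       frac_adapter = 0,
                       frac_n = 0,
                       track_molecules = FALSE,
                       cluster_programs = NULL,
                       seed = 1L) {
  cfg <- list(
    n_cells_per_cluster = n_cells_per_cluster, n_genes = as.integer(n_genes),
    depth_range = depth_range, nb_dispersion = nb_dispersion,
    marker_effect = marker_effect,
    proliferative_fraction = proliferative_fraction,
    planted_signature_genes = planted_signature_genes,
    planted_emp_genes = planted_emp_genes,
    planted_ubiquitous_genes = planted_ubiquitous_genes,
    planted_de = planted_de,
    n_private_markers = as.integer(n_private_markers),
    n_shallow_cells = as.integer(n_shallow_cells),
    mito_tpm = mito_tpm,
    pcr_duplication_mean = pcr_duplication_mean,
    seq_error_rate = seq_error_rate,
    frac_adapter = frac_adapter, frac_n = frac_n,
    track_molecules = isTRUE(track_molecules),
    cluster_programs = cluster_programs,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  ncc <- cfg$n_cells_per_cluster
  if (is.null(names(ncc)) || any(!nzchar(names(ncc))))
    stop("n_cells_per_cluster must be a named vector")
  if (any(ncc <= 0) || any(ncc != round(ncc)))
    stop("cell counts must be positive integers")
  if (cfg$n_genes <= 0) stop("n_genes must be positive")
  if (length(cfg$depth_range) != 2 || any(cfg$depth_range <= 0) ||
      diff(cfg$depth_range) < 0)
    stop("depth_range must be two increasing positive bounds")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$marker_effect < 1) stop("marker_effect must be >= 1")
  pf <- cfg$proliferative_fraction
  if (any(pf < 0 | pf > 1)) stop("proliferative fractions must lie in [0,1]")
  if (cfg$pcr_duplication_mean < 1) stop("pcr_duplication_mean must be >= 1")
  for (f in c("seq_error_rate", "frac_adapter", "frac_n"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0,1]")
  progs <- cluster_program_map(cfg)
  known_panels <- names(panel_genes(cfg))
  for (cl in names(progs)) {
    bad <- setdiff(names(progs[[cl]]), known_panels)
    if (length(bad))
      stop("cluster '", cl, "' references unknown marker panel: ",
           paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# The special gene panels of the synthetic universe.
panel_genes <- function(cfg) {
  list(
    endothelial = c("Pecam1", "Cdh5", "Kdr", "Cldn5"),
    arterial = c("Dll4", "Igfbp3", "Unc5b", "Gja4", "Hey1", "Mecom",
                 "Efnb2", "Epas1", "Vegfc", "Cxcr4"),
    venous = c("Nr2f2", "Nrp2", "Aplnr"),
    hematopoietic = c("Ptprc", "Spn", "Itga2b", "Gata1", "Klf1", "Lmo2"),
    mesenchymal = c("Col1a1", "Acta2", "Pdgfrb", "Dlk1"),
    signature = cfg$planted_signature_genes,
    emp = cfg$planted_emp_genes
  )
}

mito_gene_names <- function() {
  paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Co3",
                  "Atp6", "Atp8", "Cytb", "Nd4", "Nd5"))
}

# Default per-cluster marker programs (panel name -> fold multiplier).
# HEC keeps partial arterial identity (sqrt of the full effect).
cluster_program_map <- function(cfg) {
  if (!is.null(cfg$cluster_programs)) return(cfg$cluster_programs)
  e <- cfg$marker_effect
  defaults <- list(
    vEC = c(endothelial = e, venous = e),
    earlyAEC = c(endothelial = e, arterial = e),
    lateAEC = c(endothelial = e, arterial = e),
    pEC = c(endothelial = e),
    pAEC = c(endothelial = e, arterial = e),
    HEC = c(endothelial = e, arterial = sqrt(e), signature = e, emp = e),
    HC = c(hematopoietic = 8 * e),
    Neg = c(mesenchymal = e)
  )
  progs <- defaults[intersect(names(defaults), names(cfg$n_cells_per_cluster))]
  progs
}

# Deterministic nucleotide encoding of a non-negative integer, big-endian
# base 4 over the alphabet ACGT, fixed width.
int_to_seq <- function(i, width, alphabet = c("A", "C", "G", "T")) {
  out <- matrix(alphabet[1L], nrow = width, ncol = length(i))
  x <- as.integer(i)
  for (pos in width:1) {
    out[pos, ] <- alphabet[(x %% 4L) + 1L]
    x <- x %/% 4L
  }
  apply(out, 2, paste, collapse = "")
}

#' Deterministic gene tag sequences
#'
#' Each gene is identified in synthetic reads by a unique 20-nt tag, so gene
#' assignment is an exact lookup and no alignment is needed. Tags are the
#' base-3 encoding of the gene index over C/G/T: they contain no A at all, so
#' the polyA trimmer can never eat into a tag.
#'
#' @param genes character vector of gene names.
#' @return named character vector tag sequences.
#' @export
gene_tags <- function(genes) {
  alphabet <- c("C", "G", "T")
  width <- GENE_TAG_LENGTH
  if (length(genes) > 3^width) stop("gene tag space exhausted")
  out <- matrix(alphabet[1L], nrow = width, ncol = length(genes))
  x <- seq_along(genes) - 1L
  for (pos in width:1) {
    out[pos, ] <- alphabet[(x %% 3L) + 1L]
    x <- x %/% 3L
  }
  tags <- apply(out, 2, paste, collapse = "")
  names(tags) <- genes
  tags
}

#' Sample-barcode assignment for a set of cells
#'
#' @param cells character vector of cell names.
#' @return named character vector of distinct 8-nt barcodes.
#' @export
cell_barcodes <- function(cells) {
  if (length(cells) > 4^BARCODE_LENGTH)
    stop("more cells than available 8-nt barcodes")
  bc <- int_to_seq(seq_along(cells), BARCODE_LENGTH)
  names(bc) <- cells
  bc
}

build_gene_table <- function(cfg) {
  panels <- panel_genes(cfg)
  special <- data.frame(
    gene = c(panels$endothelial, panels$arterial, panels$venous,
             panels$hematopoietic, panels$mesenchymal,
             read_panel(system.file("extdata", "g1s_genes.txt",
                                    package = "hecscreen", mustWork = TRUE)),
             read_panel(system.file("extdata", "g2m_genes.txt",
                                    package = "hecscreen", mustWork = TRUE)),
             panels$signature, panels$emp, cfg$planted_ubiquitous_genes,
             mito_gene_names()),
    role = c(rep("endothelial", length(panels$endothelial)),
             rep("arterial", length(panels$arterial)),
             rep("venous", length(panels$venous)),
             rep("hematopoietic", length(panels$hematopoietic)),
             rep("mesenchymal", length(panels$mesenchymal)),
             rep("g1s", 43), rep("g2m", 54),
             rep("signature", length(panels$signature)),
             rep("emp", length(panels$emp)),
             rep("ubiquitous", length(cfg$planted_ubiquitous_genes)),
             rep("mito", 10)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(special$gene))
    stop("planted gene lists overlap the built-in panels")
  base_tpm <- c(endothelial = 8, arterial = 5, venous = 5, hematopoietic = 2,
                mesenchymal = 8, g1s = 6, g2m = 6, signature = 8, emp = 8,
                ubiquitous = 300, mito = cfg$mito_tpm)
  special$baseline_tpm <- unname(base_tpm[special$role])
  n_filler <- cfg$n_genes - nrow(special)
  if (n_filler < cfg$n_private_markers * length(cfg$n_cells_per_cluster))
    stop("n_genes too small for the special panels and private markers")
  filler <- data.frame(
    gene = sprintf("Gene%05d", seq_len(n_filler)),
    role = "filler", baseline_tpm = NA_real_, stringsAsFactors = FALSE
  )
  rbind(special, filler)
}

#' Simulate a deduplicated UMI count dataset with ground truth
#'
#' Draws per-cell depths log-uniformly within `depth_range`, builds
#' per-cluster expected expression profiles from the marker programs and the
#' configured plants, perturbs cell-cycle program genes per cell according to
#' the planted phase, and samples counts by a gamma-multinomial scheme
#' (gamma gene weights, multinomial conditioned on the exact depth), whose
#' per-gene marginals are negative-binomial-like with the configured
#' dispersion while column totals match the drawn depths exactly.
#'
#' Mitochondrial ("mt-") genes belong to the universe and, when tracked, to
#' the molecule table, but are excluded from the returned count matrix, which
#' is defined as what exact UMI deduplication can observe.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (sparse genes x cells dgCMatrix), `metadata`
#'   (per-cell data.frame) and `truth` (list: `cell_cluster`,
#'   `molecule_table` or NULL, `planted_de`, `planted_phase`, `gene_table`,
#'   `barcodes`).
#' @export
simulate_count_dataset <- function(config) {
  validate_sim_config(config)
  local_seed(config$seed, {
    gt <- build_gene_table(config)
    n_filler <- sum(gt$role == "filler")
    # filler abundances: heavy-tailed log-normal (most genes lowly expressed,
    # a few dominating), scaled so all baselines sum to 1e6 TPM
    filler_w <- exp(rnorm(n_filler, 0, 2))
    special_mass <- sum(gt$baseline_tpm, na.rm = TRUE)
    gt$baseline_tpm[gt$role == "filler"] <-
      filler_w / sum(filler_w) * (1e6 - special_mass)

    clusters <- names(config$n_cells_per_cluster)
    progs <- cluster_program_map(config)
    panels <- panel_genes(config)

    # private markers: distinct filler genes per cluster, elevated at
    # marker_effect, replacing the paper's unmodelled per-cluster programs
    filler_names <- gt$gene[gt$role == "filler"]
    private <- list()
    if (config$n_private_markers > 0) {
      pool <- rev(filler_names)
      for (i in seq_along(clusters)) {
        idx <- ((i - 1) * config$n_private_markers + 1):(i * config$n_private_markers)
        private[[clusters[i]]] <- pool[idx]
      }
    }

    # per-cluster expected TPM profiles
    profile <- matrix(gt$baseline_tpm, nrow = nrow(gt), ncol = length(clusters),
                      dimnames = list(gt$gene, clusters))
    planted_de <- list()
    for (cl in clusters) {
      pr <- progs[[cl]]
      for (panel in names(pr)) {
        g <- intersect(panels[[panel]], gt$gene)
        profile[g, cl] <- profile[g, cl] * pr[[panel]]
        if (pr[[panel]] > 1)
          planted_de[[length(planted_de) + 1L]] <- data.frame(
            gene = g, cluster = cl, direction = "up", fold = pr[[panel]],
            stringsAsFactors = FALSE)
      }
      if (!is.null(private[[cl]]) && config$marker_effect > 1) {
        profile[private[[cl]], cl] <- profile[private[[cl]], cl] * config$marker_effect
        planted_de[[length(planted_de) + 1L]] <- data.frame(
          gene = private[[cl]], cluster = cl, direction = "up",
          fold = config$marker_effect, stringsAsFactors = FALSE)
      }
    }
    if (!is.null(config$planted_de)) {
      pd <- config$planted_de
      if (!all(pd$gene %in% gt$gene)) stop("planted_de names unknown genes")
      if (!all(pd$cluster %in% clusters)) stop("planted_de names unknown clusters")
      for (i in seq_len(nrow(pd)))
        profile[pd$gene[i], pd$cluster[i]] <-
          profile[pd$gene[i], pd$cluster[i]] * pd$fold[i]
      planted_de[[length(planted_de) + 1L]] <- data.frame(
        gene = pd$gene, cluster = pd$cluster,
        direction = ifelse(pd$fold >= 1, "up", "down"), fold = pd$fold,
        stringsAsFactors = FALSE)
    }
    planted_de <- if (length(planted_de)) do.call(rbind, planted_de) else
      data.frame(gene = character(), cluster = character(),
                 direction = character(), fold = numeric())

    # cells, depths, planted phases
    cell_cluster <- rep(clusters, config$n_cells_per_cluster)
    cells <- unlist(lapply(clusters, function(cl)
      sprintf("%s_%03d", cl, seq_len(config$n_cells_per_cluster[[cl]]))))
    depth <- round(exp(runif(length(cells), log(config$depth_range[1]),
                             log(config$depth_range[2]))))
    shallow <- rep(FALSE, length(cells))
    if (config$n_shallow_cells > 0) {
      sc <- sprintf("shallow_%03d", seq_len(config$n_shallow_cells))
      cells <- c(cells, sc)
      cell_cluster <- c(cell_cluster, rep(clusters[1], config$n_shallow_cells))
      depth <- c(depth, round(runif(config$n_shallow_cells, 2e4, 6e4)))
      shallow <- c(shallow, rep(TRUE, config$n_shallow_cells))
    }
    names(cell_cluster) <- cells

    pf <- config$proliferative_fraction
    frac <- ifelse(cell_cluster %in% names(pf), pf[cell_cluster], 0)
    cycling <- runif(length(cells)) < frac
    phase <- rep("quiescent", length(cells))
    phase[cycling] <- sample(c("G1", "S", "G2M"), sum(cycling), replace = TRUE)
    names(phase) <- cells

    # per-cell expected profiles: cluster profile + phase program on the
    # cell-cycle panels (S cells get an extra G1/S boost so the planted
    # G1/S score exceeds the G2/M score)
    mu <- profile[, cell_cluster, drop = FALSE]
    colnames(mu) <- cells
    g1s_idx <- which(gt$role == "g1s")
    g2m_idx <- which(gt$role == "g2m")
    e <- config$marker_effect
    mu[g1s_idx, phase == "G1"] <- mu[g1s_idx, phase == "G1"] * 1.5 * e
    mu[g1s_idx, phase == "S"] <- mu[g1s_idx, phase == "S"] * 2 * e
    mu[g2m_idx, phase == "S"] <- mu[g2m_idx, phase == "S"] * 1.5 * e
    mu[g2m_idx, phase == "G2M"] <- mu[g2m_idx, phase == "G2M"] * 1.5 * e

    # gamma-multinomial sampling
    d <- config$nb_dispersion
    lam <- matrix(0, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    pos <- mu > 0
    lam[pos] <- rgamma(sum(pos), shape = 1 / d, rate = 1 / (d * mu[pos]))
    counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
    for (j in seq_len(ncol(mu))) {
      if (sum(lam[, j]) == 0) stop("degenerate cell with zero expected mass")
      counts[, j] <- rmultinom(1, depth[j], lam[, j])
    }

    mito <- startsWith(rownames(counts), "mt-")
    out_counts <- Matrix::Matrix(counts[!mito, , drop = FALSE], sparse = TRUE)
    out_counts <- methods::as(out_counts, "CsparseMatrix")

    molecule_table <- NULL
    if (config$track_molecules)
      molecule_table <- molecule_table_from_counts(counts)

    barcodes <- cell_barcodes(cells)
    metadata <- data.frame(
      cell = cells,
      barcode = unname(barcodes),
      cluster = unname(cell_cluster),
      stage = ifelse(cell_cluster %in% c("pEC", "pAEC"), "E8.5", "E10.0"),
      location = ifelse(cell_cluster %in% c("earlyAEC", "lateAEC", "HEC"),
                        "DA", "body"),
      immunophenotype = ifelse(cell_cluster == "Neg", "non-EC",
                        ifelse(cell_cluster == "HC", "CD45+",
                               "CD31+CD41-CD43-CD45-")),
      negative_control = cell_cluster == "Neg",
      planted_shallow = shallow,
      planted_phase = unname(phase),
      depth = depth,
      stringsAsFactors = FALSE
    )

    truth <- list(
      cell_cluster = cell_cluster,
      molecule_table = molecule_table,
      planted_de = planted_de,
      planted_phase = phase,
      planted_pattern = NULL,
      gene_table = gt,
      barcodes = barcodes,
      private_markers = private
    )
    list(counts = out_counts, metadata = metadata, truth = truth)
  })
}

# Expand a genes x cells count matrix into one row per molecule, drawing
# distinct 8-nt UMIs without replacement within each (cell, gene) group so
# the distinct-UMI count equals the molecule count exactly.
molecule_table_from_counts <- function(counts) {
  nz <- which(counts > 0, arr.ind = TRUE)
  k <- counts[nz]
  if (any(k > 4^UMI_LENGTH))
    stop("a (cell, gene) group exceeds the 8-nt UMI space")
  umi_idx <- unlist(lapply(k, function(n) sample.int(4^UMI_LENGTH, n)))
  data.frame(
    cell = rep(colnames(counts)[nz[, 2]], k),
    gene = rep(rownames(counts)[nz[, 1]], k),
    umi = int_to_seq(umi_idx - 1L, UMI_LENGTH),
    stringsAsFactors = FALSE
  )
}

#' Write paired synthetic STRT FASTQ files for a simulated dataset
#'
#' Each true molecule is sequenced 1 + Poisson(mean - 1) times. Read 2 (the
#' primer read) is anchor + sample barcode + UMI + T25; read 1 (the cDNA
#' read) is TSO + gene tag + polyA. Optional junk read pairs are spiked in as
#' adapter-contaminated or N-rich cDNA reads; they carry valid barcodes so
#' only the read-QC filters can remove them. Files are gzipped 4-line FASTQ
#' (Phred+33, constant quality I).
#'
#' @param truth ground truth from [simulate_count_dataset()] run with
#'   `track_molecules = TRUE`.
#' @param config the same [sim_config()].
#' @param barcode_map named barcode vector (cell -> 8-nt barcode); defaults
#'   to the truth's assignment.
#' @param fastq1,fastq2 output paths for the cDNA and primer reads.
#' @param adapter adapter sequence used for contamination spikes.
#' @return invisibly, a data.frame describing every written read pair
#'   (`id`, `cell`, `gene`, `umi`, `spike`).
#' @export
simulate_fastq <- function(truth, config, barcode_map = truth$barcodes,
                           fastq1, fastq2, adapter = DEFAULT_ADAPTER) {
  mt <- truth$molecule_table
  if (is.null(mt))
    stop("ground truth has no molecule table; rerun simulate_count_dataset ",
         "with track_molecules = TRUE")
  if (anyDuplicated(barcode_map))
    stop("barcode collision between samples")
  if (any(nchar(barcode_map) != BARCODE_LENGTH))
    stop("barcodes must be 8 nt")
  if (!all(names(truth$cell_cluster) %in% names(barcode_map)))
    stop("every cell needs an assigned barcode")
  local_seed(config$seed + 1L, {
    copies <- 1L + rpois(nrow(mt), config$pcr_duplication_mean - 1)
    reads <- data.frame(
      cell = rep(mt$cell, copies),
      gene = rep(mt$gene, copies),
      umi = rep(mt$umi, copies),
      spike = "none",
      stringsAsFactors = FALSE
    )
    tags <- gene_tags(truth$gene_table$gene)
    r1 <- paste0(STRT_TSO, tags[reads$gene], strrep("A", 26))
    r2 <- paste0(STRT_ANCHOR, barcode_map[reads$cell], reads$umi,
                 strrep("T", 25))
    if (config$seq_error_rate > 0)
      r1 <- mutate_bases(r1, config$seq_error_rate)

    n_junk_a <- round(config$frac_adapter * nrow(reads))
    n_junk_n <- round(config$frac_n * nrow(reads))
    if (n_junk_a + n_junk_n > 0) {
      jc <- sample(names(barcode_map), n_junk_a + n_junk_n, replace = TRUE)
      ju <- int_to_seq(sample.int(4^UMI_LENGTH, n_junk_a + n_junk_n,
                                  replace = TRUE) - 1L, UMI_LENGTH)
      jr1 <- c(rep(paste0(STRT_TSO, adapter,
                          strrep("G", 21), strrep("A", 26)), n_junk_a),
               rep(paste0(strrep("N", 30), strrep("G", 24), strrep("A", 26)),
                   n_junk_n))
      jr2 <- paste0(STRT_ANCHOR, barcode_map[jc], ju, strrep("T", 25))
      reads <- rbind(reads, data.frame(
        cell = jc, gene = NA_character_, umi = ju,
        spike = rep(c("adapter", "nrich"), c(n_junk_a, n_junk_n)),
        stringsAsFactors = FALSE))
      r1 <- c(r1, jr1)
      r2 <- c(r2, jr2)
    }

    ord <- sample.int(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    r1 <- r1[ord]
    r2 <- r2[ord]
    reads$id <- sprintf("read%08d", seq_len(nrow(reads)))
    write_fastq_gz(reads$id, r1, strrep("I", nchar(r1)), fastq1)
    write_fastq_gz(reads$id, r2, strrep("I", nchar(r2)), fastq2)
    invisible(reads[, c("id", "cell", "gene", "umi", "spike")])
  })
}

# Random substitutions at the given per-base rate.
mutate_bases <- function(seqs, rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1, total, rate)
  if (n_err == 0) return(seqs)
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_i <- findInterval(pos - 1L, ends) + 1L
  within <- pos - c(0, ends)[read_i]
  for (k in seq_len(n_err)) {
    i <- read_i[k]
    j <- within[k]
    old <- substr(seqs[i], j, j)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    substr(seqs[i], j, j) <- new
  }
  seqs
}

#' Simulate log-normalized trajectory expression patterns
#'
#' Generates genes whose mean expression follows one of up to five distinct
#' profiles (monotone up, monotone down, mid peak, mid trough, late step)
#' across ordered clusters, with Gaussian noise on the log-normalized scale,
#' and records the planted pattern of every gene.
#'
#' @param n_genes number of genes.
#' @param cluster_names ordered cluster names (>= 4 for five profiles).
#' @param cells_per_cluster cells per cluster.
#' @param noise_sd Gaussian noise sd per cell on the log scale.
#' @param n_profiles number of distinct profiles to plant (<= 5).
#' @param amplitude dynamic range of the profiles on the log scale.
#' @param seed RNG seed.
#' @return list with `norm` (genes x cells matrix), `clusters` (per-cell
#'   labels in trajectory order) and `truth` (`planted_pattern`, a named
#'   integer vector).
#' @export
simulate_trajectory_patterns <- function(n_genes = 500,
                                         cluster_names = c("pEC", "pAEC",
                                                           "earlyAEC", "HEC"),
                                         cells_per_cluster = 30,
                                         noise_sd = 0.2,
                                         n_profiles = 5,
                                         amplitude = 2,
                                         seed = 1L) {
  m <- length(cluster_names)
  if (n_profiles > 5) stop("at most five planted profiles are defined")
  if (m < 4 && n_profiles >= 4)
    stop("fewer ordered clusters than the distinct profiles require")
  if (m < 2) stop("need at least two ordered clusters")
  shapes <- trajectory_profiles(m, amplitude)[seq_len(n_profiles)]
  local_seed(seed, {
    pattern <- rep_len(seq_len(n_profiles), n_genes)
    genes <- sprintf("TrajGene%04d", seq_len(n_genes))
    names(pattern) <- genes
    cl <- rep(cluster_names, each = cells_per_cluster)
    cells <- sprintf("%s_%03d", cl, sequence(rep(cells_per_cluster, m)))
    mu <- do.call(rbind, shapes[pattern])
    norm <- mu[, match(cl, cluster_names), drop = FALSE] +
      matrix(rnorm(n_genes * length(cells), 0, noise_sd), n_genes)
    norm <- pmax(norm + 1, 0)
    dimnames(norm) <- list(genes, cells)
    list(norm = norm, clusters = stats::setNames(cl, cells),
         truth = list(planted_pattern = pattern))
  })
}

trajectory_profiles <- function(m, amplitude) {
  x <- seq(0, 1, length.out = m)
  mid <- (m + 1) / 2
  bump <- exp(-((seq_len(m) - mid)^2) / (2 * (m / 4)^2))
  list(
    up = amplitude * x,
    down = amplitude * (1 - x),
    peak = amplitude * bump,
    trough = amplitude * (1 - bump),
    late_step = amplitude * as.numeric(seq_len(m) > m / 2)
  )
}
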