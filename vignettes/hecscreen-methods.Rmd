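---
title: "Methods: screening hemogenic endothelium in single-cell UMI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening hemogenic endothelium in single-cell UMI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hecscreen)
```

# The problem

Hemogenic endothelial cells (HECs) are rare aortic endothelial cells of the
mid-gestation embryo that retain arterial identity while acquiring a
hematopoietic program; the subset primed to make hematopoietic stem cells
must be distinguished both from ordinary arterial endothelium and from
yolk-sac-derived progenitors (erythro-myeloid progenitors, EMPs) that share
hematopoietic markers. `hecscreen` reimplements, as a tested and reusable
pipeline, the bespoke computations with which such cells are identified from
STRT-style single-cell UMI transcriptomes: UMI quantification from raw reads,
quality control and normalization, clustering, bipolar arteriovenous scoring,
rule-based cell-cycle staging, dual-method differential expression, the
multi-stage signature-gene screen, and expression-pattern analysis along the
specification trajectory.

Because the original embryo dataset cannot be bundled, a synthetic-data
generator with complete ground truth stands in for it. Every downstream
claim the test suite makes is a claim about recovering planted structure.

# UMI quantification

Library structure: the primer read carries a fixed anchor, an 8-nt
sample barcode, an 8-nt UMI and a poly-T stretch; the mate carries the
template-switch oligo (TSO) followed by cDNA and a polyA tail. Quantification
proceeds read-pair-wise:

1. **Read QC** — pairs whose cDNA read contains the adapter sequence, or has
   strictly more than 10% N bases, are discarded (tallied per reason).
2. **Parsing** — the barcode and UMI are cut out at fixed offsets after the
   anchor; pairs without the anchor are counted as unparseable. The cDNA read
   is stripped of its TSO prefix and of a trailing polyA run (at least 10
   bases, allowing one interior mismatch; the mismatch must have A on both
   sides so a genuine terminal cDNA base is never trimmed).
3. **Demultiplexing** — exact (0-mismatch) barcode matching. The tolerance is
   deliberately exact: it keeps the identity between the deduplicated matrix
   and the simulation ground truth testable as a strict equality.
4. **Gene assignment** — synthetic reads encode gene identity as a unique
   20-nt tag (base-3 over C/G/T, so tags contain no A and the polyA trimmer
   cannot shorten them); assignment is an exact prefix lookup. Alignment to a
   genome is out of scope.
5. **Deduplication** — the count of a gene in a cell is the number of
   distinct UMI sequences among its reads (no 1-edit UMI collapsing), and
   mitochondrial genes (`mt-` prefix) are excluded from the matrix.

A conservation identity is enforced: kept + adapter + high-N + unparseable +
unmatched + unassigned reads equals the input.

# Quality control and normalization

Cells are retained iff they have strictly more than 2,000 detected genes and
strictly more than 100,000 transcripts; genes are retained when expressed in
at least 3 cells. Expression is normalized to `log2(TPM/10 + 1)`, where TPM
is UMIs per gene scaled to one million per cell; the division by 10 reflects
that most cells contain fewer than a million molecules, so a transcript
should not be counted several times. The per-cell TPM total over retained
genes is exactly 1e6 by construction, which the tests assert to 1e-6
relative error.

# Highly variable genes, embedding, clustering

HVGs are genes with mean expression in (1, 8) — mean defined as
`log2(mean(2^x - 1) + 1)` — and bin-standardized dispersion above 1,
dispersion being variance/mean of the de-logged values. Two numerical
choices here were genuinely open and are worth stating:

* **Robust bin standardization.** Within each of 20 bins of gene mean the
  dispersion is centred and scaled by the bin *median* and *MAD* rather than
  mean and SD (the cell-ranger flavour of this convention). With a compact
  synthetic universe (3,000 genes), a handful of strongly variable planted
  programs would otherwise inflate a bin's SD and mask genuinely variable
  markers in the same bin; the robust variant makes the baseline reflect the
  unstructured genes, which is what the standardization is for.
* **Cell-cycle genes are excluded before the bin statistics are computed**,
  not merely dropped from the output list. Proliferation programs are among
  the most dispersed genes; removing them only afterwards would leave them
  polluting the baseline of every bin they occupy, defeating the purpose of
  mitigating the cell-cycle effect. The exclusion list defaults to the union
  of the G1/S and G2/M core sets as a stand-in for the full cell-cycle GO
  term membership, and any list can be supplied.

Cells are embedded on the gene-standardized HVG submatrix by PCA (top 15 PCs
by default; an elbow suggestion — the smallest component count after which
the incremental variance explained falls below 1% — is also reported).
Clustering is a k-nearest-neighbour graph (k = 20, Euclidean) partitioned by
Louvain modularity, deterministic under a fixed seed. Clusters in which the
flagged negative-control cells exceed 50% (strictly) are renamed `Neg` — a
deterministic replacement for a manual reclassification step; the threshold
guarantees the rule never relabels a majority-real cluster and never moves
cells between non-Neg clusters. Finally, `Neg` cells and cells with
normalized *Ptprc* or *Spn* above 1 are removed before endothelial analyses.

# Arteriovenous score and cell-cycle phases

The bipolar arteriovenous score uses 10 arterial markers (*Dll4*, *Igfbp3*,
*Unc5b*, *Gja4*, *Hey1*, *Mecom*, *Efnb2*, *Epas1*, *Vegfc*, *Cxcr4*) and 3
venous markers (*Nr2f2*, *Nrp2*, *Aplnr*). Three steps: scale each marker to
0–10 across cells (min to 0, max to 10; a constant gene maps to all zeros —
a stated convention for the degenerate case), average the scaled values per
cell within each panel, and rescale each per-cell average to 0–10. A score
of 5 is the classification threshold (strict: a cell at exactly (5, 5) is
"neither"). Per-cluster 50% confidence ellipses come from the fitted
bivariate normal at the chi-square(2 df) quantile. The whole construction is
invariant to per-gene increasing affine transforms of the input, which the
tests check.

Cell-cycle scores are the mean log-normalized expression of a 43-gene G1/S
set and a 54-gene G2/M set (the Tirosh core sets, shipped as editable
one-gene-per-line panels in mouse nomenclature). The phase rule: both scores
below 2 means quiescent; otherwise, G2/M score above G1/S means G2M, G1/S
above G2/M means G1 if the G2/M score is below 2 and S otherwise. The rule
as stated leaves an exact proliferative tie undefined; ties are assigned G2M
so the rule is total and deterministic. Scores are computed on all retained
genes, not an HVG-restricted set.

# Differential expression and the signature screen

Two-group calls gate genes on detection (nonzero in at least 25% of one of
the groups), then use

* **Wilcoxon**: two-sided rank-sum P, Bonferroni-adjusted by default
  (Benjamini–Hochberg by flag); and
* **ROC**: AUC = probability a random target-group cell exceeds a random
  comparison cell (ties counted half), classifier power `2|AUC - 0.5|`,
  called at power >= 0.4 (configurable; no published cutoff exists for this
  step).

Both use fold change computed on de-logged group means, `(mean(2^x - 1) +
0.01) / (...)`, with significance requiring fold >= 2 and adjusted P <=
0.05. The screen then proceeds: a gene is HEC-*overrepresented* when both
methods call it up-regulated against *every* comparison cluster (vEC,
earlyAEC, lateAEC, HC); overrepresented candidates are then dropped if they
are on the EMP exclusion list (*Gsta4*, *Spi1*, *Alox5ap*, *Myb*), if their
per-cluster summary in HEC is below 2, or if that summary exceeds 2 in every
cluster. The summary statistic is the per-cluster **median** (the natural
reading of ordering genes by their median expression in the target); each
dropped gene records its reason, and the stages are nested by construction.

# Expression patterns

For more than two clusters, DEGs come from one-way ANOVA with Tukey's HSD
per cluster pair (adjusted P < 0.05 and de-logged fold > 2 or < 0.5; the
fold gate uses the same de-logged convention as the two-group calls). Genes
changed in at least one of the two branch-versus-reference comparisons are
assigned to one of the 3 x 3 - 1 = 8 directional classes (direction in
branch 1 by direction in branch 2, the doubly-unchanged class excluded).
The class order is fixed and documented (branch-1 direction major: up, down,
unchanged; branch 2 minor) because no machine-readable mapping of the
original Roman-numeral patterns exists.

Along an ordered trajectory, the top DEGs are consensus-clustered: 100
k-means runs (k = 5) on 80% gene subsamples of the row-z-scored profiles,
co-clustering frequencies among co-sampled pairs forming the consensus
matrix, which is cut into 5 groups by average linkage. All DEGs are then
reassigned to the pattern whose member genes have the maximal average
Pearson correlation with the gene's profile (ties to the lowest pattern id;
constant profiles are flagged unassignable). Regulon-overlap testing is a
one-sided Fisher exact test against the expressed-gene universe with BH
adjustment at 0.05; it equals the brute-force hypergeometric tail to 1e-10,
which the tests assert. Gene-set activity is the first principal component
of the set's submatrix with the sign corrected to correlate positively with
the per-cell set mean; heat-map style smoothing is a centred moving average
with truncated edge windows.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, and
its defaults are the package's study conditions:

* **Clusters and sizes**: vEC 60, earlyAEC 80, lateAEC 80, HEC 60, HC 40,
  Neg 40 (pEC/pAEC available for trajectory work), named cells with
  metadata (stage, location, immunophenotype, negative-control flag).
* **Depths**: log-uniform between 1e5 and 3e6 UMIs per cell, matching the
  order-of-magnitude spread of deep STRT libraries.
* **Counts**: gamma-multinomial — per-cell gamma gene weights (shape
  1/dispersion) and a multinomial draw conditioned on the exact depth. The
  per-gene marginals are negative-binomial-like with dispersion 0.4 (a free
  parameter; no empirical dispersion is published for the original data),
  while column totals match the drawn depths exactly, which keeps the QC
  accounting and the dedup oracle exact.
* **Baseline abundances**: heavy-tailed log-normal (sd 2 on the log scale),
  so most genes are lowly expressed and a few dominate, as in real
  transcriptomes; special genes get fixed baselines (markers ~5–8 TPM,
  ubiquitous genes 300 TPM).
* **Programs**: endothelial markers in all EC clusters; arterial markers in
  earlyAEC/lateAEC/pAEC at the full marker effect and in HEC at its square
  root (partial arterial identity); venous markers in vEC; a strong
  hematopoietic program (including *Ptprc*/*Spn*) in HC; a mesenchymal
  program in Neg; 11 signature genes and the 4 EMP genes elevated only in
  HEC; 15 private marker genes per cluster for separability. The default
  marker effect is 20-fold: arteriovenous and lineage markers are
  near-exclusive between vessel beds in real data, and a fold of this size
  is what makes the planted markers genuinely "highly variable" against the
  generator's baseline noise.
* **Cell cycle**: cluster-specific proliferative fractions (HEC 0.8, HC 0.6,
  lateAEC 0.05, others ~0.2–0.3); cycling cells elevate the G1/S and/or
  G2/M program so that the planted phase is recoverable by the score rule
  (G1: G1/S x1.5e; S: G1/S x2e and G2/M x1.5e; G2M: G2/M x1.5e).
* **Reads**: one pair per sequenced copy (copies 1 + Poisson), with optional
  substitution errors and spiked junk pairs (adapter-contaminated or N-rich)
  that carry valid barcodes so only the read-QC filters can remove them.
  UMIs are sampled without replacement within each (cell, gene) group, so
  distinct-UMI counting recovers the molecule count exactly.

What the generator does **not** emulate: doublets, ambient RNA, batch
effects, chemistry-specific error profiles, UMI collisions (by the
without-replacement choice), or realistic transcript-level structure (gene
identity is a tag; alignment is out of scope). Passing tests therefore
demonstrate the pipeline's correctness and calibration on data satisfying
its own assumptions, not robustness to artefacts absent from the model.

# Problem sizes and numerical conventions

The reference dataset is 3,000 genes by 360 cells — large enough that every
filter, score and screen operates away from small-sample edge cases, small
enough that the full test suite runs in minutes. The FASTQ demonstration
uses 50 cells by 500 genes at 1,000–5,000 UMIs per cell with duplication
mean 5 (~680k read pairs), the package's demo scale for molecule-level round
trips. The trajectory generator plants 5 profiles (monotone up, monotone
down, mid peak, mid trough, late step) over 4 ordered clusters with Gaussian
noise (sd 0.2) on the log scale.

Other conventions: strict inequalities follow the stated thresholds
everywhere (a cell with exactly 2,000 genes fails QC; Ptprc exactly 1 is
kept; a score of exactly 5 is not arterial); zero-variance genes are skipped
with a note in the ANOVA; all-tied rank-sum tests carry no evidence (P set
to 1); gzipped outputs are written with a zero-mtime header so fixed seeds
give byte-identical files; every stochastic step takes an explicit seed and
the pipeline manifest records parameters and md5 of every output.

# Known limitations

* The TF and surfaceome annotation lists (1,485 TFs; 871 high-confidence
  surface proteins) are database-derived inputs and are not redistributed;
  `annotate_genes()` takes any user-supplied lists, and the tests use
  synthetic ones.
* The cell-cycle GO exclusion list defaults to the union of the shipped
  G1/S and G2/M core panels, a stand-in for the full GO term membership.
* Graph clustering reproduces the class of method (kNN + modularity), not
  any third-party tool's exact labels; correctness is asserted against
  planted structure (ARI), not label identity.
* The consensus-clustering parameters (100 reps, 80% subsampling,
  average-linkage cut) follow the referenced tool's defaults; only k = 5
  and the k-means core are prescribed.
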