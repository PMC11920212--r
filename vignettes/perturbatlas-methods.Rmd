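---
title: "Methods: genotype assignment, cell states and transcriptional heterogeneity in yeast Perturb-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype assignment, cell states and transcriptional heterogeneity in yeast Perturb-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbatlas)
```

# Overview

`perturbatlas` implements the computational core of a genome-scale yeast
Perturb-seq analysis built on an RNA-barcoded knockout collection. Each
deletion strain expresses a 20-nt genotype barcode and a 5-nt clone barcode
in the 3'UTR of the selection marker, so a cell's genotype can be read from
its own transcriptome and from a targeted amplicon library. Downstream, the
package discovers transcriptional cell states, tests which genotypes act as
state attractors, quantifies per-cell transcriptional heterogeneity with an
SVD leverage score, classifies core versus stress-responsive states across
conditions, and tests whether genotype sets carry a fitness cost.

Every stage is exercised end-to-end on a synthetic-data generator with
known ground truth, so the whole pipeline is testable without any external
download.

# The barcode cassette

The expressed cassette places, after the marker's stop codon: a 5-nt clone
barcode, a 43-nt constant terminator linker, the 20-nt genotype (Downtag)
barcode, and a 17-nt constant downstream flank. The 85-nt artificial contig
(`YKO_CONTIG_TEMPLATE`) concatenates these segments with the barcode slots
as N-runs. Two anchor sequences locate the genotype barcode in amplicon
reads: D2 is the terminal 18 nt of the linker and D1 is the 17-nt flank.
With a 20-nt primer prefix on the amplicon read, the clone barcode occupies
read positions 21–25, D2 starts at position 51 and D1 at position 89 —
inside the positional acceptance windows (48–51 and 85–90) used by the read
filter. The D1/D2 anchors are not printed explicitly anywhere; defining
them as the terminal linker segment and the flank is the one choice that
reproduces the stated windows exactly.

Cassette integrity at the genomic level is checked by
`validate_locus()`: the median distance between 3'UTR reads and the
annotated stop codon of the deleted gene must not exceed 300 bp (strictly
greater medians fail). Medians of even-length samples use the midpoint
convention.

# Genotype and clone assignment

`find_pattern()` scans every window of a read for an anchor allowing up to
3 substitutions (Hamming distance only; indels are not modeled — reads with
indels fail the positional windows anyway). When an anchor matches more
than once, the match with the maximum start position wins
(`select_anchor()`). Reads missing either anchor, or whose anchors fall
outside the positional windows, are dropped with a reason code.

The region between the D2 anchor end and the D1 anchor start is compared
against the barcode library at up to 2 mismatches (`call_genotype()`);
because the library guarantees pairwise barcode distance of at least 5,
a unique call is always well-defined for error-free reads. Zero hits or two
or more hits yield no call — a deliberately conservative rule that protects
precision.

Per cell, reads vote with the strict 70% rule (`aggregate_cell()`): a cell
observing multiple genotypes is assigned only when one genotype exceeds 70%
of the genotype-informative reads, otherwise it is discarded. Votes are
cast over UMI-deduplicated reads by default (a flag restores raw-read
voting). The same rule applies to the expression-matrix route
(`matrix_call()`, UMI counts over `bc-` contigs). `merge_sources()`
reconciles the two routes: agreement keeps the genotype, disagreement marks
the cell conflicted (omitted downstream), and a single-route call is
accepted. The clone is the majority clone among reads supporting the
assigned genotype; ties resolve to the lexicographically smallest clone and
are flagged — an arbitrary but deterministic convention.

# Cell states

Quality control keeps cells whose detected-gene count lies within ±2 SD of
the population mean and whose mitochondrial read fraction is at most 10%.
Normalization is per-cell depth scaling to 10,000 counts followed by
`log1p`; ribosomal genes can be masked out at this step. This package uses
plain log normalization rather than a regularized negative-binomial
transform: every downstream statistic in scope (rank tests, PCA/SVD
geometry, module scores) operates on any log-scale matrix, and a plain,
parameter-free transform keeps results transparent and reproducible. The
choice is recorded in the pipeline configuration.

Cell-cycle handling follows the standard bin-matched control scheme:
`score_module()` scores the S and G2M gene programs against controls drawn
from expression-matched bins, `assign_phase()` labels each cell (G1 when
both scores are non-positive), and `regress_out()` removes the scores by
per-gene ordinary least squares, leaving residuals orthogonal to the
covariates (checked to |r| < 1e-8).

Highly variable genes are ranked by standardized variance: a loess fit of
log10 variance on log10 mean (span 0.3, degree 2) predicts each gene's
expected SD; observed deviations are scaled by it, clipped at sqrt(n), and
their variance ranks the genes. The gene-count default is 2000.

Clustering runs PCA (14 components by default) on the standardized HVG
matrix, builds a shared-nearest-neighbor graph (20 neighbors, Jaccard
weights, pruned below 1/15) and optimizes modularity with Louvain at
resolution 1. Labels are renumbered by decreasing cluster size; a fixed
seed makes the whole path deterministic.

Markers are one-vs-rest two-sided Wilcoxon rank-sum tests per gene, BH
adjusted within each state's test set, with log2 fold changes computed on
de-logged means with a 1e-9 pseudocount (configurable); upregulated markers
require log2FC > 0.25 at adjusted p < 0.05. The Wilcoxon implementation
uses exact enumeration for small groups (combined n ≤ 16, ties handled by
enumerating the observed ranks) and a tie-corrected normal approximation
with continuity correction otherwise.

Differential expression between two cell groups applies independent
filtering: genes with zero counts in both groups are removed, a grid of 100
mean-expression quantiles is scanned, and for each threshold the BH
adjustment runs only on passing genes. The threshold that maximizes the
number of significant genes is chosen, smallest first on ties. The chosen
threshold is verified in the tests by exhaustively recounting over the
grid. Genome-wide DE counts use |log2FC| ≥ 1 at p < 0.05.

Clone-level DE compares each clone with more than 9 cells against its
genotype's other clones (those with at least 3 cells), within genotypes
deeper than 200 cells, reporting DEGs at adjusted p < 0.05 per comparison.

`score_signature_rank()` scores signatures from expression ranks alone:
ranks beyond 1500 are clipped, and the score is `1 - U/(n * r_max)` floored
at zero. Note a boundary subtlety: when every signature gene lies beyond
the rank ceiling the clipped-rank formula yields `(n-1)/(2*r_max)` (about
1e-3), not exactly zero; the floor matters only for larger sets.

# Genotype-by-state enrichment

For every genotype with at least 6 cells and every state, a 2x2 table (in
state and genotype / out of either / both margins fixed) is tested with a
two-sided Fisher exact test. The p-value sums hypergeometric probabilities
of tables at least as improbable as the observed one; the odds ratio is the
sample cross-product ratio, with a flagged Haldane–Anscombe +0.5 correction
only when a cell is zero — a deterministic, transparent choice over the
conditional-MLE estimate. BH adjustment spans all genotype-by-state tests
of a condition by default (the conservative scope; per-state adjustment is
available behind a flag). Enrichment requires OR > 1 at adjusted p < 0.05;
depletion OR < 1 at adjusted p < 0.05 (an odds ratio cannot be negative, so
the depletion side is necessarily the OR < 1 regime).

# Transcriptional heterogeneity

The leverage score works plate by plate on log-normalized expression
restricted to genes with raw mean count strictly above 0.25 (raw means by
default; a flag switches to normalized means):

1. the top 20 left singular vectors of the cells-by-genes matrix are
   computed by partial SVD (`irlba`; dense SVD below a size cutoff, and k
   is reduced to min(k, n-1, g-1) with a record when a plate is small);
2. each cell's raw leverage is the squared row norm of the singular-vector
   matrix; plate scores are normalized to sum to 1;
3. scores are log-transformed (natural log — the base cancels in the
   z-score) and z-scored against the plate's wild-type cells.

Per genotype (≥ 6 cells), the sample SD of the scaled leverage is divided
by the pooled wild-type SD so wild type equals exactly 1 — pooling across
plates after per-plate z-scoring is the only definition that yields a
single wild-type reference value. Genotypes at ≥ 1.3 are negative
regulators of heterogeneity (their loss increases it), ≤ 0.7 positive
regulators.

# Cross-condition analysis

Marker-set conservation between conditions is tested per state pair with a
two-sided Fisher test on the overlap of upregulated marker sets against a
common gene universe, BH adjusted across pairs.

Label transfer is implemented as PCA projection plus k-nearest-neighbor
majority vote: the stress-program markers (or any exclusion set) are
removed from both datasets, both are renormalized, components are fit on
the reference, the query is projected, and each query cell takes the
majority state among its 30 nearest reference cells (ties go to the single
nearest neighbor). The scientific contract — each query cell receives the
reference state it most resembles — is preserved without an anchor-based
integration step, and the transfer map records row-stochastic proportions
in both directions. A reference state is "core" when at least 40% of its
transferred cells concentrate in one query state (the modal counterpart;
an exclusive-pairing variant was considered and rejected as underdefined),
or when manually listed as an override.

The fitness test compares a genotype set's mean score per stressor against
1000 random equal-size draws from the unclassified genotypes, one-sided,
with the add-one convention p = (1 + extreme)/(n_perm + 1) so p is never
zero and bottoms out at 1/1001. The test direction is a required argument
rather than a default, since "worse fitness" depends on the scale of the
input table.

# The synthetic-data generator

`gen_library()` draws genotype barcodes by rejection sampling at pairwise
Hamming distance ≥ 5, guaranteeing unambiguous calls at ≤ 2 mismatches.
`gen_amplicon_fastq()` writes paired reads — 16-nt cell barcode + 12-nt UMI
on read 1, primer + cassette on read 2 — with iid substitutions and a
configurable fraction of ambient reads carrying another genotype (which
exercises the 70% rule). Base qualities are written as constant Q40; PCR
duplicates, UMI collisions and indels are not modeled.

`gen_counts()` draws gamma-Poisson (negative binomial) counts with
log-normal cell size factors, organized by:

- **latent cell states** (default K = 5, uniform mixture) with marker
  programs elevated `marker_effect`-fold (default 4);
- **knockout silencing**: the deleted gene keeps 2% of its wild-type mean
  (deletions reduce, but do not always abolish, detectable expression);
- **state attractors**: listed genotypes place probability `pi_target`
  (default 0.6) on a target state;
- **a stress program** elevated under the stress condition;
- **latent co-expression programs** (default 20 programs of 8 genes) whose
  per-cell activation varies log-normally (SD 0.6, i.e. typical 2–4-fold
  swings — the magnitude of program variability seen for stress and
  cell-cycle programs in scRNA-seq) and which span the top singular
  subspace the leverage score reads;
- **variance-inflated genotypes** with partial penetrance: each cell of an
  inflated genotype is deviant with probability 0.5, and deviant cells
  widen their program-activation SD by `het_inflation` (default 3).

The penetrance structure deserves a note. Early designs inflated every
cell of a genotype uniformly — either a global expression scale or the
activation SD of all programs. Neither is detectable by the leverage SD:
a global scale cancels in depth normalization, and a uniform inflation
only shifts the mean of log leverage because the SD of a scaled squared
norm is scale-invariant (chi-square concentration). What the per-genotype
leverage SD actually measures is how differently a genotype's cells
deviate — a wide distribution needs a mixture of near-normal and strongly
deviant cells. Partially penetrant deviation is therefore both the
mechanism that makes inflation detectable and a faithful picture of the
biology: perturbations that increase heterogeneity spread a population
across transcriptional space rather than moving it as a block.

What the generator does **not** emulate: doublets and empty wells, ambient
mRNA in the expression matrix (ambient reads exist only in the amplicon
library), batch effects beyond plate identity, mean–variance trends more
complex than NB with shared dispersion, bursty transcription, and real
yeast regulon structure. Passing tests demonstrate that the algorithms
recover planted structure under this model, not that the model reproduces
every property of real data.

# Numerical choices and degenerate inputs

- Seeds are explicit everywhere; a master seed derives per-stage seeds.
  A fixed configuration reproduces counts and FASTQ byte-identically.
- QC with zero SD of detected genes keeps all cells passing the mito rule.
- Cells with zero total counts abort normalization with their barcodes.
- Collinear regression covariates abort with the offending names.
- `plate_leverage` reduces k for small plates and records the reduction;
  plates without ≥ 2 wild-type cells, or with zero WT leverage variance,
  abort by name.
- Fisher tables with any zero cell flag the Haldane correction; all-zero
  tables are errors.
- Independent-filtering ties break toward the smaller threshold.
- Louvain clustering of an all-identical matrix returns a single cluster.

# Problem sizes

The test suite and the acceptance script run desk-scale cohorts chosen to
make every recovery property measurable with comfortable margins: 100
cells per genotype (the coverage scale of the real screens), 300–500 genes,
20 genotypes for assignment (500 knockout cells at 10 reads/cell), 60
genotypes for attractor recovery, and 20 seeded replicates of an
11-genotype single-plate cohort for heterogeneity recovery. The complete
suite runs in well under a minute.

# Known limitations

- The amplicon parser assumes substitution-only errors; indel-bearing
  reads are rejected by the positional filters rather than rescued.
- Cell-barcode whitelist correction and UMI-network deduplication are out
  of scope; the simulated chemistry is idealized (16 + 12 nt, exact).
- Label transfer is a PCA/k-NN re-implementation, not an anchor-based
  integration; with strong batch effects between conditions the projection
  can be biased in ways anchor methods partially correct.
- The cell-cycle gene lists are inputs, not shipped knowledge; phase
  assignment quality depends entirely on the supplied lists.
- The amplicon layout parameterizes the primer prefix length (default 20)
  because the exact primer boundary of the published 102-bp amplicon is
  not printed; all positional defaults assume the 20-nt prefix.
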