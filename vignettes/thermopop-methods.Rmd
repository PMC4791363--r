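---
title: "Methods: recovering and characterizing hot-spring genome populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering and characterizing hot-spring genome populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermopop` re-implements, as a tested and reusable pipeline, the desk
work of recovering population genomes from low-coverage shotgun
metagenomes of thermal-spring streamer communities and characterizing
them: composition binning, read-recruitment abundances, marker-based
completeness, ANI/AAI/16S relatedness, marker-gene phylogeny support,
COG-profile ordination, and identity-threshold occurrence surveys. This
vignette records the model behind each stage, the tunable parameters
with their defaults and rationale, the numerical conventions, and what
the synthetic-data generator does and does not emulate.

## The synthetic-community generator

Every stage of the pipeline is exercised against communities with
*planted truth*, produced by the generator rather than downloaded data.
The generator's defaults encode the conditions of the communities this
pipeline targets, and they are deliberately not tuned per analysis:

* **Genomes** (`simulate_genome()`): i.i.d. base draws with per-position
  G+C probability equal to the population's `gc_target`. Distinct
  populations in these communities sit at well-separated G+C anchors
  (e.g. 44 % vs 29 %), which is what makes composition binning work.
  An optional k-mer bias layer builds the genome in 200-bp chunks and
  keeps, among `max_tries = 30` candidate chunks, one drawn with
  probability proportional to the product of the relative weights of
  its k-mers. Product weighting (rather than, say, the mean weight) is
  what makes a weight-*w* k-mer roughly *w*-fold enriched per
  occurrence; with sparse biased k-mers a mean-weight acceptance ratio
  differs from uniform only in the third decimal and produces no
  detectable compositional shift. Symmetric biases leave G+C on target.
* **Conspecific pairs** (`diverge_pair()`): independent per-site
  substitution with probability 1 − target identity, no indels. This
  keeps the true identity analytic — the planted value is recoverable
  by alignment to within binomial error — at the cost of realism
  (real conspecific genomes also differ by indels and rearrangements).
* **Contigs** (`fragment_and_cover()`): non-overlapping substrings with
  lengths ≥ `min_len` and per-contig coverage drawn around `cov_mean`
  (`cov_sd = 0.4`). The communities this emulates were assembled at
  roughly 2–3.5× genome coverage; the coverage *dispersion* is not
  reported anywhere, so it is an exposed parameter rather than a fixed
  constant.
* **Reads** (`simulate_reads()`): Sanger-like lengths, normal with mean
  820 bp (`len_sd = 120`, truncated at 50 bp and at the genome length),
  drawn from genomes proportional to abundance × genome length, half on
  the minus strand, substitution errors only. A truth table
  (read → source genome, position, strand) is always returned.
* **Proteomes** (`simulate_proteome()`, `diverge_proteome()`): uniform
  i.i.d. residues, lengths 100–500 aa so intact best-hit pairs can pass
  a 100-residue alignment filter; divergence again substitution-only.
* **Surveys** (`simulate_survey()`): site temperature and pH uniform in
  the global ranges (defaults 70–90 °C and pH 7–9, the terrestrial
  thermal-spring window these phylotypes occupy); each phylotype has a
  niche window, and pools carry a 16S variant at `identity_in = 0.99`
  inside the niche and `identity_out = 0.93` outside — both at exact
  planted substitution counts placed away from the gene ends, so the
  alignment identity equals the planted value and straddles a 97 %
  threshold with ≥ 2 % margin on each side.

What the generator does *not* emulate: chimeric reads, quality scores,
indel or rearrangement divergence, strain microdiversity beyond a single
divergence parameter, assembly artifacts, and database contamination.
Passing recovery tests on these communities therefore shows that the
*computations* are correct and calibrated, not that the pipeline is
robust to every pathology of real survey data.

All generators take an explicit integer seed and are byte-reproducible.
`stage_seed(master, stage)` derives per-stage seeds deterministically
from one master seed and a stage name, so pipelines driven from one seed
never entangle the random streams of different stages.

## Composition binning

Contigs are represented by canonical word-frequency vectors
(`word_frequency()`): sliding windows of width *k* at step 1, each
window pooled with its reverse complement (the strand of an assembled
contig is arbitrary), windows containing ambiguous bases skipped, counts
normalized to sum to 1. The default *k* = 4 (tetranucleotides, 136
canonical classes) is the standard choice for composition binning and is
small enough that a 3-kbp contig still estimates the vector usefully.

`project_pca()` mean-centers the vectors (no scaling — the entries
share a scale) and projects onto principal components ordered by
explained variance; contigs of length ≤ 3000 bp are excluded first,
matching the "> 3 kbp" screen under which composition is stable enough
to separate populations. `assign_bins()` then runs seeded k-means
(`stats::kmeans`, 10 starts) in the concatenated feature space of
standardized PC coordinates ⊕ G+C ⊕ log coverage. The original
population assignments in this kind of analysis were partly drawn by
eye on the PCA plot; seeded k-means with a distance-based orphan rule is
the reproducible stand-in. A contig farther from its nearest cluster
centre than the 97.5th percentile of within-cluster distances is
labelled `ORPHAN` — by construction this sets aside roughly the 2.5 %
least-typical contigs rather than forcing them into bins. Bins are
relabelled by decreasing size so output names are deterministic.

## The alignment engine

All BLAST-like steps go through one internal aligner (`local_align()`,
Rcpp): Smith–Waterman local alignment with linear gap costs. Below a
DP-size cutoff (4 × 10⁶ cells) the exact full dynamic program runs; above
it, shared k-mers between query and subject (k = 11 nt / 4 aa, k-mers
occurring > 64 times in the subject skipped as repeats) vote for
diagonals, and a banded DP runs around the best diagonal window
(band = 50 for pairwise use; 16 for read recruitment and 32 for ANI
fragments, where the synthetic truth is substitution-only and the
diagonal is exact). Tie-breaking is fixed everywhere — first maximal
cell in row-major order; diagonal > gap-in-subject > gap-in-query — so
results are deterministic and the seeded and exact paths agree whenever
the optimal alignment lies inside the band. The test suite checks the
engine against an independently written plain-R exhaustive DP and
against `Biostrings::pairwiseAlignment` scores.

DNA scoring defaults to +1/−1 with gap −2 (−3 where spurious gaps are
costlier than mismatches, i.e. recruitment and ANI fragments); protein
scoring uses BLOSUM62 with linear gap −8. The banded DP treats the
virtual subject column 0 as a zero-score start anchor so alignments
beginning at a sequence edge are found exactly.

**16S identity** (`rrna_identity()`) is deliberately *not* local: a
local alignment between unrelated genes collapses onto a short perfect
island and reports near-100 % identity, and a free-end-gap overlap
alignment has the same defect at the matrix corners (a one-column
perfect match outscores the negative full-span path). Identity is
therefore computed over the optimal *global* (Needleman–Wunsch)
alignment with penalized end gaps — the only convention under which a
">97 %" occurrence threshold means what it is meant to mean for
full-length genes. Sequences under 200 bp are compared with a warning.

## Read recruitment

`recruit_reads()` aligns each read (both strands; the reverse strand is
tried when the forward hit fails the thresholds) against every bin's
concatenated references and takes the best score. A read is assigned
only if its identity (matches / alignment columns) *strictly exceeds*
`min_identity = 0.90` — the threshold is quoted as ">90 % nt ID", so a
read at exactly 90 % is an orphan — and at least `min_cov = 0.5` of the
read aligns (the minimum-coverage floor prevents short spurious seeds
from dominating; the source analyses are silent on this, so it is
exposed). Equal best scores in two bins orphan the read: deterministic
and conservative, matching the semantics of an "unassigned" category.
`abundance_table()` reports per-bin read percentages (always including
the `ORPHAN` row, summing to 100), and `gc_histogram()` the per-bin G+C
frequency tables with an `ALL` series.

## Completeness and assembly statistics

`marker_fraction()` scores an annotation table against a single-copy
marker catalog: a marker is present iff at least one annotated gene —
*partial fragments count* — carries its label, and presence is binary
per marker (multiple fragments of one gene count once).
`completeness_report()` takes exactly three catalogs (by default the
conventional 21 tRNA synthetase / 40 universal / 178 bacterial
housekeeping sets) and reports each fraction and their unweighted mean
as a percentage. The bundled catalog contents under `inst/extdata/` are
editable placeholders — the 21 tRNA synthetase symbols are real gene
names, the other two lists are synthetic labels, because the published
catalog contents live in external references; the computation is
independent of the labels, and real analyses should supply their own
lists. Marker detection is consumed from annotation tables, not
computed by homology search — gene prediction and annotation are
upstream of this package.

## ANI and AAI

`pairwise_ani()` follows the fragment convention: the query genome is
cut into 1000-bp windows advanced by 200 bp, each fragment locally
aligned to the subject (better strand kept), and a fragment retained
when its alignment is ≥ 700 bp, ≥ 70 % identical, and covers ≥ 70 % of
the fragment; ANI is the mean ± sd of retained identities and is
*undefined* (a signal distinct from an error) below 50 retained
fragments. The parameter set printed in the source description of this
calculator is internally inconsistent (it lists "window size = 100 bp"
twice next to "step size = 200 bp"); the established fragment-ANI
dialect consistent with the 700-bp minimum — window 1000, step 200 — is
adopted, and every parameter is a function argument.

`pairwise_aai()` computes bidirectional best hits on the symmetric
local-alignment score matrix (ties broken toward the lexicographically
smaller partner id) and retains pairs passing three filters: identity
≥ 30 %, alignment covering ≥ 70 % of the subject protein, alignment
≥ 100 residues. Two readings were fixed where the source wording is
ambiguous: "similarity" in the first filter is implemented as percent
*identity* (the only reproducible reading without a fixed similarity
grouping), and best hits are bidirectional rather than one-way. The
description of AAI as a percentage of *differing* residues is treated
as an erratum — the reported values for near-identical genomes (~94 %)
are only consistent with percent identity.

## Marker phylogeny

`curate_references()` retains genomes carrying ≥ 16 of the 18 marker
genes (five universal, thirteen bacterial-specific), with a whitelist
for taxa kept despite missing genes. `concatenate_partitions()` joins
per-gene alignments in lexicographic gene order (determinism), gap-fills
taxa missing a gene, and counts informative positions (columns with ≥ 2
distinct non-gap states). Column confidence weights — the internal
stand-in for external weighting tools, a documented deviation rather
than a reproduction — are (fraction non-gap) × (modal residue frequency
among non-gap), down-weighting gappy and ambiguously aligned columns.

Tree estimation replaces the external partitioned maximum-likelihood
pipeline with corrected-distance neighbor joining: weighted p-distances
over columns where both taxa are non-gap, corrected by
d = −((s−1)/s) · ln(1 − s·p/(s−1)) with s = 20 for proteins and s = 4
(Jukes–Cantor) for nucleotides, saturated pairs (p ≥ (s−1)/s) capped at
`max_dist = 10`. `nj_tree()` delegates the agglomeration to `ape::nj`
(taxa pre-sorted lexicographically so input order cannot change the
result; negative branch lengths clamped at 0; the three-taxon case uses
the closed-form three-point solution). `bootstrap_support()` resamples
columns with replacement *within each partition*, re-runs distance + NJ
per replicate, and reports the percentage of replicates containing each
original bipartition (`ape::prop.clades`, unrooted). This reproduces
the curation, concatenation, weighting and support *semantics* of the
original analyses; it does not reproduce ML topologies or branch
lengths.

`csi_scan()` locates a conserved signature indel by its two flanking
motifs in each taxon's ungapped sequence; the indel length is the
residue count strictly between the flanks minus the signature's
reference span, `NOT_FOUND` when a flank is absent, and an error when a
flank matches twice (the signature is then ill-posed). Signature
definitions are user-supplied — the published signature alignments are
not reproduced here.

## COG profiles and ordination

`cog_matrix()` builds a binary genome × COG matrix over the union of
observed COGs (which COG universe the source analyses used is unstated;
the observed union is adopted — absent columns would be all-zero and
carry no distance information anyway). Euclidean distance between
presence rows equals √(Hamming distance), a closed form the tests
exploit.

`nmds()` minimizes Kruskal stress-1 by monotone regression and
iterative majorization (`vegan::monoMDS`, global model) from one
classical-scaling start (`cmdscale`) plus 20 seeded random restarts,
returning the best configuration; convergence thresholds are set tight
(`smin = 1e-12`, `sfgrmin = 1e-12`, 1000 iterations) so exactly
embeddable distances reach numerically zero stress. Ties are treated as
*secondary* by default — tied dissimilarities must receive equal fitted
distances. Under the more common primary (weak) treatment, a fully tied
distance matrix (e.g. four mutually equidistant genomes) has stress
identically zero because ties impose no order constraints at all, which
silently hides exactly the non-embeddable structure the stress is meant
to flag; `ties = "primary"` remains available for compatibility.
`pathway_completeness()` is set arithmetic over editable gene-list
definitions (`inst/extdata/pathways.tsv` ships glycolysis, oxidative
TCA and a 30-gene cobalamin-synthesis list as examples).

## Ecological distribution

`occurrence_call()` takes the best global-alignment 16S identity
between a phylotype reference and each site's sequence pool and calls a
positive occurrence only when it *strictly exceeds* the threshold
(default 97 %): the source wording is ">97 %", so an identity of
exactly 97.0 % is negative, and the threshold is an argument for anyone
preferring the inclusive reading. Raising the threshold can only remove
positives (monotonicity, tested). Temperature or pH ranges in site
metadata are collapsed to their arithmetic means.

`kruskal_wallis()` wraps the tie-corrected rank-sum test
(`stats::kruskal.test`) and adds an optional exact permutation p-value
that enumerates all distinct assignments of the pooled observations to
the group sizes while the multinomial count stays ≤ 2 × 10⁵ (all
ordinary small-sample designs; degenerate cases such as ten singleton
groups exceed the bound and fall back to Monte Carlo with a warning).
`pearson_r()` wraps `stats::cor.test`. `test_env_distributions()` joins
occurrence calls with site metadata and compares the temperature and pH
of positive sites across phylotypes.

## Numerical conventions and degenerate inputs

* Identity is always matches / alignment columns; ambiguous bases never
  count as matches and are excluded from G+C and skipped in k-mer
  windows. A sequence with no unambiguous bases has undefined G+C
  (error).
* ANI/AAI results with too few retained comparisons are *undefined*
  objects (`defined = FALSE`, `NA` statistics), not errors — downstream
  code can distinguish "no signal" from "bad input".
* Empty read sets recruit to an empty table; zero reads make an
  abundance table undefined (error). Empty site pools give negative
  occurrence calls with `NA` identity.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state (`withr::with_seed`).

## Problem sizes used in the tests

The recovery tests run at sizes chosen to put sampling error well below
the tolerances they assert: 6 × 10⁵-bp genomes and 100 contigs per
population for binning (adjusted Rand index vs planted truth), 10⁴
error-free 820-bp reads over four populations for abundance recovery
(binomial error ≪ 2 percentage points), 10⁶-bp genomes for ANI recovery
at planted identities 0.99–0.80 (fragment sd ≈ 0.6 points), 200-protein
proteomes for AAI, 500 random pairs ≤ 200 nt for the aligner-oracle
comparison, 100 random additive trees for quartet recovery, and 10⁴
null replicates for the Kruskal–Wallis type-I calibration. The
acceptance script (`scripts/acceptance.R`) re-runs the same scenarios
from one master seed and writes every measured quantity as JSON.

## Known limitations

* Binning is single-sample composition + coverage; differential
  coverage across samples and modern ML binners are out of scope.
* The aligner's seeded path can miss optima whose alignment leaves the
  diagonal band (large indels); for the substitution-only synthetic
  truth this cannot happen, but divergent real data with long indels
  deserve a wider `band`.
* NJ with corrected distances is a topology stand-in, not a replacement
  for partitioned ML inference; bootstrap supports are supports of the
  NJ estimator.
* Completeness, COG and pathway calls are annotation-table lookups; the
  package neither predicts genes nor searches for homologs, and its
  placeholder catalogs must be replaced for real data.
* The exact Kruskal–Wallis permutation p is enumerative only for small
  designs; the χ² p is the default beyond them.
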