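---
title: "Detecting microbial gene expression in host RNA-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microbial gene expression in host RNA-seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Short-read RNA-seq of human tissue contains a small admixture of reads of
bacterial and viral origin. microseek implements an alignment-free route
from raw reads to cohort-level microbial biology: a convolutional
classifier assigns each read a probability of human, viral or bacterial
origin; high-scoring reads seed a greedy assembly of microbial contigs;
contigs are annotated against nucleotide and protein references; and a
statistics layer compares feature prevalence across cohorts, corrects for
confounding, and screens features against survival. This vignette explains
each model, its assumptions, the parameters that matter, and the
deliberate design choices, in the package's own terms.

## The read-origin classifier

Reads are represented one-hot (76 positions x 4 bases). The network has
exactly two convolutional layers and one fully-connected hidden layer
before a three-way softmax:

    conv(64 filters, width 8, ReLU) -> max-pool(2)
    -> conv(32, width 8, ReLU) -> global max-pool
    -> dense(64, ReLU) -> dense(3, softmax)

trained with cross-entropy and Adam (`learning_rate` 1e-3, `batch_size`
128). Model selection keeps the per-epoch checkpoint with the highest
mean one-vs-all area under the precision-recall curve (AUPRC) on the
validation split. The implementation is native vectorized R: convolution
is an im2col reshape followed by a BLAS matrix multiply, and the backward
pass is hand-derived and verified against numerical differentiation in
the test suite. At fixture scale (a few thousand segments) training takes
well under a minute per epoch.

Training data come from labeled reference sequences cut into 76-base
segments. Two details matter:

* **Split before segmenting.** References are assigned to
  train/validation/test *before* segmentation, so overlapping segments of
  one reference can never leak across splits.
* **Per-class strides** (human 26, viral 2, bacterial 130) equalize
  per-class segment counts when the class total lengths are roughly in
  13 : 1 : 65 proportion — the situation of a host transcriptome, a small
  viral transcript collection, and a large bacterial genome collection.
  Segments containing `N` are dropped.

Reads reaching the scorer pass through fixed normalization rules: reads
with more than one `N` are excluded; a single `N` is replaced by a random
base *for scoring only*; 75-base reads get one random 3' base to reach
the 76 the model expects. Stored read sequences are never altered — the
randomized sequence exists only on the scoring path, and the replacement
base is recorded (`n_fill`) so that downstream steps can reuse it.

## Seed-and-extend assembly

Every read whose bacterial or viral score reaches `seed_threshold`
(default 0.46, surfaced as a parameter) is a seed. Seeds are processed
bacterial-first (descending bacterial score), then viral (descending
viral score); a read at or above threshold on both is classed bacterial.
Extension is greedy and exact: at each contig end, candidate reads
overlapping by at least `min_overlap` (default 24) with a perfect match
— `N` matching anything on either side, the non-`N` base always kept —
are found through a hash index of read prefixes/suffixes, and the read
giving the longest extension wins (ties: higher seed-class score, then
read id). Each read joins at most one contig.

Choices the method text leaves open, decided here:

* **Longest-extension greedy choice** with deterministic tie-breaks;
  mismatch-tolerant overlap is deliberately *not* offered, because only
  the `N` wildcard rule is part of the method.
* **Containment absorption.** When extension stops, unused reads wholly
  contained in the contig are absorbed as members and consumed. Without
  this, the reads tiling an already-reconstructed transcript would seed
  many duplicate partial contigs; with it, a planted transcript at
  20x coverage yields exactly one contig.
* **No reverse-complement overlaps**: reads are treated single-stranded.
* `max_contig_length` 2000 bounds run time; transcripts at desk scale
  are shorter.
* An `N` never covered by a non-`N` base is finally replaced by the same
  random base used when the read was scored, and the contig is flagged
  `unresolved_N`.

On fixtures with planted 400-800 base bacterial transcripts at 20x
coverage (75-base reads, 0.005 per-base `N` rate), essentially all
transcripts are recovered by a contig at >= 99% identity over >= 80% of
their length; the acceptance script recomputes this rate.

## Contig annotation

The default search backend is a built-in ungapped seed-and-extend local
aligner: shared words (11-mers for nucleotide, exact 3-mers for protein)
define diagonals, and the best ungapped segment on a diagonal is the
maximum-sum subarray of per-position substitution scores (+2/-3 for
nucleotide; BLOSUM62 for protein, with stop codons scored -30 so
translated alignments cannot cross a stop). Significance follows
Karlin-Altschul statistics, `E = K m n exp(-lambda S)`: `lambda` is
solved numerically from the scoring scheme under uniform background
(protein: the standard ungapped BLOSUM62 constants lambda = 0.3176,
K = 0.134). E-values from the built-in aligner are approximate — `K` for
the nucleotide scheme is a standard order-of-magnitude constant — but
monotone in score, which is all top-hit ranking requires. An external
BLAST+ backend (`backend = "blast"`) is available behind the same
interface; the test suite checks that the two backends agree on top-hit
accessions for high-identity fixture contigs.

Per contig and search type exactly one hit is retained: lowest e-value,
ties broken by bit score then accession. Nucleotide hits below e-value
0.01 carry species and genus; translated six-frame hits below 1e-5 carry
a protein family and reading frame. Hits to configured contaminant
genera are screened out and logged. Species-level presence is pooled to
genus presence per sample to reduce the number of hypotheses.

## Cohort statistics

**Presence matrices.** Samples pool to patients by OR: a patient is
positive for a feature if any of their samples is. Features tested in
the binomial path must be present in at least 10% of cases or 10% of
controls (boundary inclusive).

**Differential prevalence.** For each feature, the null probability is
the control-cohort prevalence clamped into [0.0001, 0.9999] (exact 0 or
1 would force a zero p-value), the direction is "greater" or "less"
according to the sign of the case-control prevalence difference, and the
p-value is the one-tailed binomial tail over the case count. p-values
are corrected by Benjamini-Hochberg FDR.

**Confounder correction.** A boosted logistic regression (gradient
boosting with logistic loss; depth-2 trees, 200 rounds, learning rate
0.05) estimates each patient's probability of case membership from race,
age, sex, weight, smoking and sequencing depth. Propensities are
**cross-fitted** (5-fold out-of-fold predictions): in-sample fitting
with this much boosting capacity overfits badly enough that pure-noise
covariates score AUC near 0.8 and the resulting weights actively
unbalance the cohorts, while out-of-fold propensities restore both the
chance-level null AUC and weight quality. Weights are the inverse
probability of the observed cohort, truncated at the [1st, 99th]
percentiles and stabilized to mean 1, and each feature is tested by a
chi-squared statistic on the weight-summed 2x2 table. The plain weighted
Pearson statistic ignores weight variability and is anti-conservative
(its type-I error roughly doubles under realistic weight spread), so an
effective-sample-size variant (`ess_correction = TRUE`, Kish ESS per
cohort) is provided; it reduces exactly to the plain statistic at unit
weights, and it is what the calibration experiment uses. No prevalence
filter applies in this path: all features with any abundance are tested.

**Survival screens.** Features with at least 5 positive and 5 negative
patients (after dropping patients without clinical data) are tested by a
two-group log-rank statistic per endpoint (overall, disease-free), with
BH correction within endpoint over tested features. The log-rank
implementation is the direct observed-minus-expected form with
hypergeometric variance; the test suite requires agreement with an
independent reference implementation (`survival::survdiff`) to 1e-8.

**Host expression screens.** Genes are z-scored across patients. A gene
is called upregulated in a presence-defined patient group when the
two-sided rank-sum p-value (normal approximation with tie correction) is
below 0.05 *and* the positive group's median z exceeds 0.2 *and* the
negative group's median z is below 0 — all three thresholds are exposed
as arguments with these defaults. Over-representation of user-supplied
gene sets in the selected genes uses the one-sided hypergeometric tail
with BH correction; no live pathway service is contacted.

## The synthetic-data generator

The generator defines the package's study conditions; it emulates the
*structure* of the real inputs, not their content.

* **Origin models** are order-2 Markov chains over A/C/G/T with
  well-separated transition preferences (human-like: repeat-previous
  with CpG depletion, GC 0.45; viral-like: AT-rich homopolymer runs, GC
  0.38; bacterial-like: cyclic base walk, GC 0.62). Each chain is
  calibrated by root-finding so its stationary GC equals the target.
  This yields a learnable composition signal analogous to genomic k-mer
  signatures; it does **not** reproduce real genome structure, gene
  content, or shared ancestry, so classifier performance on these
  fixtures says nothing quantitative about real-data AUPRC.
* **Reads** follow the standard shotgun model: per planted transcript,
  `Poisson(coverage x L / read_length)` reads at uniform positions, plus
  host reads drawn from the human-labeled references, with independent
  per-base `N` corruption (no substitution-error model, single-end only,
  constant quality `I`).
* **Cohorts.** Covariate effects are cohort-conditional standardized
  shifts (location shifts for continuous covariates, logit shifts for
  binary/categorical), so nonzero effects create genuine confounding —
  a propensity model on the covariates reaches AUROC above 0.7 under
  the default effect sizes. Survival times are exponential per endpoint
  with hazard `baseline x exp(sum(log-HR x presence))` and independent
  exponential censoring calibrated to the requested censoring fraction.
* **The calibration experiment** for the confounder correction uses 250
  patients per arm, covariate effects of 0.8 on age, weight and smoking,
  and a feature whose presence logit is
  `0.3 z_age + 0.3 z_weight + 0.5 smoking - 0.4` — marginally strongly
  associated with cohort, conditionally null. These values were fixed
  once as a realistic moderate-confounding regime.

## The standard end-to-end fixture

Two cohorts of 10 patients (one sample each; the first case patient has
a second, empty sample to exercise patient pooling). Three bacterial
genera are planted with distinct prevalence patterns (case-enriched
8/10 vs 1/10; balanced 5/10 vs 5/10; control-enriched 1/10 vs 7/10),
plus one viral transcript per arm's last patient. The balanced genus
carries a protein family planted in exactly five case patients, whose
presence carries a log-3 hazard ratio on survival — so that family, and
only it, satisfies the 5-positive/5-negative screen rule among cases.
Planted transcripts are 500-800 bases at 20x coverage, 75-base reads,
`N` rate 0.005, 300 host reads per sample. The pipeline writes every
stage product (score tables, contig FASTA, membership, hit tables,
presence matrices, statistics) plus a JSON run report of per-stage
counts; re-running with the same configuration and seed is byte-identical.

Problem sizes throughout (segment counts near 3000, 20 planted
transcripts, 500-replicate calibration experiments, 10 + 10 patients in
the fixture) were chosen as the smallest scales at which each property
is statistically meaningful.

## Numerical and reproducibility notes

* One root seed fans out to per-stage child seeds via a fixed string
  hash (`derive_seed`), so any stage re-run in isolation reproduces its
  in-pipeline stream.
* Ties are resolved deterministically everywhere (max-pool to the left,
  seed ordering by read id, top hits by bit score then accession).
* AUROC uses average ranks (half credit for tied scores); AUPRC
  integrates precision through tied blocks with the continuous
  interpolation, so a perfect scorer attains exactly 1.
* Degenerate inputs have defined behavior: empty read sets score to
  empty tables, an empty database warns and leaves contigs unassigned,
  a zero weighted margin or an all-censored log-rank reports a missing
  p-value rather than an error.

## Known limitations

* Markov-chain fixtures cannot calibrate real-data classifier
  performance; the published-scale AUPRCs require the real reference
  databases.
* The built-in aligner is ungapped; indel-containing homology is
  underscored relative to BLAST+ (which can be selected instead).
* The assembler ignores reverse-complement overlaps and mismatch
  tolerance by design.
* The IPW chi-squared with plain reference is anti-conservative under
  variable weights; use `ess_correction = TRUE` when calibration
  matters.
* Endpoints are fixed to overall and disease-free survival; input labels
  must be mapped to these two.
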