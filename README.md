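# microseek

Alignment-free detection and cohort analysis of microbial (bacterial and
viral) gene expression in short-read human RNA-seq.

Human tissue RNA-seq carries a trace of reads from resident microbes.
Finding them by alignment is hard: the reads are 75–76 bases, microbial
databases are enormous, and short-read alignment at that scale is both
slow and imprecise. microseek takes the alignment-free route:

1. **Read-origin classification.** A small convolutional network (two
   convolutional layers and one fully-connected layer over a one-hot
   76 × 4 encoding) assigns each read a probability triple
   (p_human, p_viral, p_bacterial), trained on reference sequences
   segmented with per-class strides (human 26, viral 2, bacterial 130)
   after a split-before-segmentation partition. Model selection maximizes
   mean one-vs-all AUPRC on the validation split.
2. **Score-guided assembly.** Reads with bacterial or viral score ≥ 0.46
   seed greedy bidirectional extension (exact overlap ≥ 24 bases, N as a
   wildcard with the non-N base kept), bacterial seeds first.
3. **Annotation.** Contigs get a top nucleotide hit (e-value < 0.01 →
   species/genus, pooled to genus) and a top translated six-frame protein
   hit (e-value < 1e-5 → protein family), via a built-in ungapped
   Karlin–Altschul aligner or BLAST+.
4. **Cohort statistics.** Patient-level presence matrices (samples pooled
   by OR); one-tailed binomial prevalence tests against the clamped
   control prevalence p0 ∈ [0.0001, 0.9999] with BH FDR;
   confounder-corrected analysis via boosted-logistic propensities
   (cross-fitted), inverse-probability weights and weighted chi-squared
   tests; presence-based log-rank survival screens under a
   5-positive/5-negative rule; rank-sum host-gene screens with
   hypergeometric gene-set enrichment.

Real patient cohorts are access-controlled, so the package ships a
first-class synthetic-data module: order-2 Markov origin models with
calibrated GC, shotgun read simulation with N corruption, and confounded
cohort/survival generators. Every pipeline stage is exercised end-to-end
on these fixtures.

## Worked example

```r
library(microseek)

models <- default_origin_models()
refs <- rbind(
  make_references(models["human"],     16, c(2000, 2600), 1),
  make_references(models["viral"],     16, c(250, 350),   2),
  make_references(models["bacterial"], 16, c(11000, 13000), 3))
ds    <- build_dataset(refs, segmentation_config(), rng_seed = 5)
model <- train_classifier(ds, classifier_config(epochs = 4, rng_seed = 7))
evaluate_classifier(model, ds$test)$metrics
#> # A tibble: 3 × 3
#>   class     auprc auroc
#>   <chr>     <dbl> <dbl>
#> 1 human     0.999 0.999
#> 2 viral     0.999 1.000
#> 3 bacterial 1.000 1
```

The three rows are one-vs-all areas under the precision–recall and ROC
curves on held-out reference segments: the network separates the three
synthetic composition classes nearly perfectly (chance on this balanced
set is AUPRC ≈ 0.33, AUROC = 0.5). Scoring, assembly and annotation then
chain directly — here a 574-base bacterial transcript is planted at 20×
coverage into a background of 300 host reads:

```r
transcripts <- make_references(models["bacterial"], 3, c(500, 800), 4)
transcripts$accession <- sub("BAC", "TRX", transcripts$accession)
sp     <- sample_spec("S1", "P1", "case", planted = c(TRX_0001 = 20),
                      read_length = 75, n_rate = 0.005,
                      host_read_count = 300, rng_seed = 9)
reads  <- make_reads(sp, rbind(refs, transcripts))
kept   <- filter_host_reads(reads, refs)
scored <- score_reads(model, kept, rng_seed = 10)
asm    <- assemble_sample(scored, assembly_params())
asm$contigs[, c("contig_id", "seed_class", "n_reads", "flags")]
#> # A tibble: 6 × 4
#>   contig_id seed_class n_reads flags
#>   <chr>     <chr>        <int> <chr>
#> 1 ctg0001   bacterial      137 .
#> 2 ctg0002   viral            1 unresolved_N
#> 3 ctg0003   viral            1 unresolved_N
#> 4 ctg0004   viral            1 unresolved_N
#> 5 ctg0005   viral            1 unresolved_N
#> 6 ctg0006   viral            1 unresolved_N
```

The first contig reconstructs 570 of the transcript's 574 bases from 137
reads; the single-read "viral" contigs are host reads whose one-N random
replacement nudged them over the 0.46 seed threshold — exactly the kind
of noise the downstream e-value cutoffs leave unassigned.

or run the whole configured study at once:

```r
run_pipeline(default_pipeline_config(rng_seed = 1), out_dir = "run1")
```

which writes per-sample score tables, contigs, hit tables, presence
matrices, the three statistical analyses and a JSON run report, and is
byte-identical across reruns of the same seed. A thin shell front end is
provided in `exec/microseek` (`simulate`, `score`, `assemble`,
`annotate`, `run-all`).

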