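# tfscout

Predicts the target genes of a transcription factor (TF) by requiring
two independent lines of evidence to agree: a binding-site signal in
the gene's promoter, and an expression correlation with the TF somewhere
across a panel of sample cohorts (e.g. cancer types).

**Who it is for:** computational biologists who have (i) a genome and
TSS annotation, (ii) a JASPAR-style binding matrix for their TF,
(iii) a genes × samples expression matrix with a sample→cohort mapping,
and optionally (iv) ChIP-seq peaks to benchmark against.

## The method

*Motif evidence.* The promoter (default the 5000 bp upstream of the
TSS, strand-aware) is scanned base by base with a log2-odds position
weight matrix $a_{bj}$ built from the PFM counts with a
background-weighted pseudocount. Every length-$n$ window
$x_1 \ldots x_n$ (both strands by default) scores
$k = \sum_i a_{m(x_i),i}$, and each gene is summarised by

- `k_max1` — best window score,
- `k_max3` — sum of the three best,
- `k_total` — sum over all windows.

*Expression evidence.* For each candidate gene the Pearson correlation
with the TF is computed within every cohort; the **R-score** is the
maximum across cohorts, capturing regulation that manifests only in
some cellular contexts.

*Prediction.* A gene is called a target when it passes both cutoffs
(strict `>`; absolute values such as `R > 0.7, k_max1 > 8`, or
percentiles of the observed scores such as `pct(75)`).

*Evaluation.* Against a ChIP-seq reference set C (peaks filtered at
fold change > 1.5 and ≥ 10 reads, then assigned to genes by
promoter-window overlap), predictions P within the gene universe A are
scored by sensitivity $|C\cap P|/|C|$, specificity
$(|A|-|C|-|P|+|C\cap P|)/(|A|-|C|)$, precision $|C\cap P|/|P|$ and the
relative prediction count $P/C$, plus an ROC/AUC sweep over R-score
cutoffs.

A seeded synthetic-benchmark generator plants exact motif copies and
known TF–target correlations so the whole pipeline is testable without
any external downloads.

## Worked example

On a synthetic data set with 10 planted targets among 200 genes
(4 cohorts × 80 samples, within-cohort correlation 0.8, one planted
consensus site per target):

```r
library(tfscout)

cfg <- sim_config(seed = 42, n_genes = 200, n_true_targets = 10,
                  n_groups = 4, samples_per_group = 80,
                  promoter_length = 1000, genes_per_chrom = 50)
pfm  <- simulate_pfm(cfg)
ga   <- simulate_genome_and_annotation(cfg, pfm)
expr <- simulate_expression(cfg, ga$truth)
ref  <- assign_peaks_to_genes(
  filter_peaks(simulate_peaks(cfg, ga$truth, ga$annotations)),
  ga$annotations, window_upstream = 1000)
ref
#> ChIP-seq reference set for TF: 10 gene(s)
#>   peaks: 30 in, 10 assigned, 20 intergenic

res <- run_tf_pipeline(ga$genome, ga$annotations, pfm, expr, "TF1",
                       cutoffs = cutoff_spec(r_cutoff = 0.45, pwm_cutoff = 8),
                       upstream_length = 1000, reference = ref)
head(res$predictions[, c("gene_id", "r_score", "best_group", "k_max1", "pass_all")], 5)
#>   gene_id   r_score best_group   k_max1 pass_all
#> 1   g0024 0.8954490      grp03 14.05944     TRUE
#> 2   g0128 0.8767753      grp02 14.05944     TRUE
#> 3   g0200 0.8627301      grp03 14.05944     TRUE
#> 4   g0074 0.8573645      grp03 14.05944     TRUE
#> 5   g0047 0.8505180      grp03 14.05944     TRUE
res$roc
#> ROC over 202 cutoff(s); AUC = 1.0000
```

Reading the output: every planted target's R-score (~0.85–0.90) is the
maximum over four within-cohort correlations of a signal planted at
0.8, and `k_max1 = 14.06` is the self-score of the planted consensus —
the maximum attainable window score for this matrix. All 10 predicted
genes are planted targets (sensitivity, specificity and precision all
1.0 on this easy, well-separated benchmark; real data are far harder —
see the methods vignette).

The same workflow is scriptable from a shell via the thin CLI in
`inst/cli/tfscout` (`simulate`, `score-pwm`, `correlate`,
`build-reference`, `evaluate`, `predict`).

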