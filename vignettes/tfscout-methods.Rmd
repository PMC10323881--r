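---
title: "Predicting TF target genes from promoter motif scores and pan-cancer expression correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TF target genes from promoter motif scores and pan-cancer expression correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcription factor (TF) regulates a set of target genes, but neither
of the two standard evidence sources identifies that set reliably on its
own. Genomic-binding evidence (ChIP-seq peaks, or position weight matrix
scans of promoter sequence) says where the factor *can* bind, which is
necessary but not sufficient for regulation. Expression evidence says
which genes *covary* with the factor, but covariation in a single tissue
is confounded and underpowered. `tfscout` combines the two: a candidate
gene must both carry a plausible binding site in its promoter and
correlate with the TF's expression somewhere across a panel of
cancer-type cohorts.

## Motif scoring of promoters

The promoter of a gene is taken as the `upstream_length` bases 5' of its
transcription start site (TSS), default **5000 bp**. The generic
promoter definition in the literature is 100–1000 bp; the wider window
deliberately trades specificity for coverage, since functional binding
sites are routinely found several kb upstream. Extraction is
strand-aware: for a minus-strand gene the window lies at higher
coordinates and is reverse-complemented, so promoters are always written
5'→3' on the coding orientation. All coordinates in the package are
0-based half-open.

A TF's binding preference enters as a position frequency matrix (PFM,
JASPAR text format), converted to a log2-odds position weight matrix
(PWM) with a background-weighted pseudocount:

$$a_{bj} = \log_2 \frac{(c_{bj} + p\,q_b)/(N_j + p)}{q_b}$$

with counts $c_{bj}$, column sums $N_j$, pseudocount $p = 0.8$ and
background $q$ uniform by default. Both are user-settable; 0.8 with a
uniform background is the convention of the motif-analysis ecosystem the
matrices come from. The scoring matrix is stored with rows in the order
A, T, C, G; `pfm_to_pwm()` performs the reordering from JASPAR's
A, C, G, T so the scanner's base-to-row mapping (A→1, T→2, C→3, G→4) is
unambiguous.

The promoter is segmented base by base into every contiguous window of
the motif length $n$ (stride 1, so a sequence of length $L$ yields
$L - n + 1$ windows). A window $x_1 \ldots x_n$ scores

$$k = \sum_{i=1}^{n} a_{m(x_i),\,i}$$

and the per-gene summaries are:

* `k_max1` — the best window score (the strongest single site),
* `k_max3` — the sum of the three best window scores (rewarding
  multiple sites),
* `k_total` — the sum over all windows (a composition-sensitive
  aggregate).

Three numerical choices matter here:

* **Both strands are scanned by default**, pooling windows of the
  sequence and of its reverse complement into one score list, since a
  binding site is a double-stranded object; `scan_reverse_strand =
  FALSE` restricts to the literal forward segmentation.
* **Windows containing `N` are skipped**, not scored: the base score is
  defined only for A/T/C/G. The count of skipped windows is reported.
* **Genes with no scorable window** (short or fully masked promoters)
  are kept with all summaries 0 and an explicit `no_windows` flag, so
  downstream joins stay total and the caller decides whether to filter.

With fewer than three windows, `k_max3` is the sum of what exists. Note
an ordering caveat: with signed log-odds matrices `k_max3` can fall
below `k_max1` when the second- and third-best windows score negative;
the familiar ordering `k_total ≥ k_max3 ≥ k_max1` is guaranteed only
for non-negative scoring matrices (e.g. probability-style matrices
supplied by the user).

## The expression R-score

For the TF and a candidate gene, the Pearson correlation of their
expression is computed within each sample group (here, cancer-type
cohorts), and the **R-score is the maximum across groups**. The maximum
— rather than a mean or a pooled correlation — encodes the biological
claim that a genuine regulatory link need only manifest in *some*
cellular context; pooling across heterogeneous cohorts would dilute it
and is vulnerable to between-cohort confounding.

Defaults and edge rules:

* The signed maximum is the default; `absolute = TRUE` maximises
  $|r|$ instead (reported as $|r|$), which surfaces targets of
  repressive factors.
* Groups with fewer than 3 samples or zero variance in either gene are
  recorded as missing with a reason code (`insufficient_samples`,
  `zero_variance`) — necessary conditions for Pearson's r to be
  defined, surfaced rather than silently dropped.
* Missing expression values are rejected at read time, keeping the
  correlation definition unambiguous (no pairwise deletion).
* The package correlates whatever values the matrix holds; any
  transformation (log, TPM, rank) is the caller's choice upstream.
* Ties between groups are broken by lexicographic group label, making
  results deterministic.

## The ChIP-seq reference set

Predictions are judged against a reference set **C** built from
ChIP-seq peaks in two steps. First, peaks are filtered by enrichment:
fold change strictly greater than 1.5 *and* at least 10 reads (the
strict/inclusive pair mirrors the "more than"/"at least" semantics of
the thresholds). Second, a gene enters C iff a passing peak overlaps
its strand-aware promoter window — `window_upstream` (default 5000 bp,
echoing the promoter definition) upstream to `window_downstream`
(default 1000 bp) downstream of the TSS. Peaks overlapping no window
are counted intergenic and discarded.

This promoter-proximity rule is a deliberate simplification of full
nearest-feature peak annotation (distal enhancers and gene-body peaks
are not assigned); users with an externally annotated target list can
load it directly with `reference_from_gene_ids()`. Finally C is
intersected with the evaluation universe (the genes present in the
expression dataset) by `restrict_to_universe()`.

## Evaluation metrics

With A the gene universe, C the reference and P the predicted set:

| metric | definition |
|---|---|
| sensitivity | $|C \cap P| / |C|$ |
| specificity | $(|A| - |C| - |P| + |C \cap P|) / (|A| - |C|)$ |
| precision | $|C \cap P| / |P|$ |
| P/C | $|P| / |C|$ |

Undefined ratios (precision with $|P| = 0$, sensitivity and P/C with
$|C| = 0$, specificity with $A = C$) are reported as `NA` and flagged —
never coerced to 0, because the behaviour of the precision sweep at
extreme cutoffs depends on the distinction.

`roc_sweep()` varies the R-score cutoff over every distinct observed
score (plus sentinels beyond both extremes), takes
$P(t) = \{g : r_g > t\}$, and traces (FPR, TPR). The AUC is the
trapezoidal area after augmenting with the (0,0) and (1,1) endpoints;
this construction equals the Mann–Whitney statistic
$\Pr(s^+ > s^-) + \tfrac12\Pr(s^+ = s^-)$, which the test suite asserts
to 1e-9 against an independent pairwise-comparison oracle and against
`pROC`.

## Prediction cutoffs

A gene is predicted when it passes both an R-score cutoff and a PWM
cutoff (on `k_max1` by default; `k_max3` or `k_total` selectable). All
comparisons are **strict** (`>`): a gene exactly at a threshold fails,
matching the phrasing of thresholds like "R > 0.7" and "k_max1 > 8"; a
switch flips to `>=`. Cutoffs may be absolute values or percentiles of
the joined table's own score distribution (e.g. `pct(75)`); percentiles
use the linear-interpolation quantile definition (R's type 7), fixed
and documented because "75th percentile" alone does not pin down a
number.

Genes with a PWM summary but no R-score (or vice versa) are excluded
from the joined table — a gene absent from the expression data cannot
be evaluated — with exclusion counts reported as attributes. The output
table is sorted by (pass, R-score, gene id) and `run_tf_pipeline()`
echoes every parameter into a run manifest.

## The synthetic benchmark

`simulate_fixture()` generates a complete, seeded test bed in the
package's own file formats. Design choices:

* **Geometry.** Each gene owns a disjoint slot (promoter + 1000 bp
  downstream margin + 250 bp intergenic tail), 100 genes per
  chromosome. Promoter windows of different genes never overlap, so
  the peak→gene assignment of a planted peak is unambiguous and the
  reference construction recovers exactly the planted truth set.
* **Motifs.** The PFM has one dominant base per column (85 of 100
  counts), and each true target receives an exact consensus copy at a
  random offset and orientation. Exact-consensus planting (rather than
  sampling from the motif model) keeps each truth gene's minimum
  attainable `k_max1` analytically known — the consensus self-score —
  so tests can assert a hard bound.
* **Expression.** The TF is standard normal per sample; a true target
  is $\rho\,x_{TF} + \sqrt{1-\rho^2}\,\varepsilon$, giving within-group
  population correlation exactly $\rho$ (default 0.8, 5 groups × 100
  samples); other genes are independent noise. Gaussian rather than
  count-distributed expression is used because Pearson's r is the
  statistic of interest and is distribution-compatible; a
  negative-binomial layer would be an extension, not a default.
* **Peaks.** One passing peak (fold change 2.0, 20 reads) near each
  true target's TSS; decoy peaks in promoters that fail the enrichment
  filter; filter-passing intergenic peaks in the tails.

The default configuration (1000 genes, 50 targets, ρ = 0.8, 5 × 100
samples, 5 kb promoters, 8 bp motif) is the package's standard
benchmark, run by `scripts/acceptance.R`. The 20-replicate precision /
P-C sweep in the test suite uses a reduced configuration (400 genes, 40
targets, 5 × 60 samples, 250 bp promoters): the swept quantities
derive only from R-scores and the peak-built reference, which promoter
length does not affect, and the smaller cohorts leave the planted/null
separation comfortably detectable while keeping the replicate loop
quick.

What the benchmark does *not* emulate — and hence what passing tests do
not show about real data: TCGA-like batch structure and cohort-size
imbalance, count-data mean–variance coupling, correlated co-regulation
among background genes, motif degeneracy and low-affinity sites,
chromatin accessibility (a scored site may be nucleosome-occluded), and
read-level ChIP-seq noise. On real inputs the separation between
targets and background is far weaker than in the planted model; the
benchmark validates the machinery, not the field performance.

## Known limitations

* Promoter-proximity peak assignment misses distal regulatory peaks.
* Sequence-only PWM scanning ignores epigenetic state.
* The R-score's maximum-over-groups is sensitive to the number of
  groups under the null (more cohorts inflate the null maximum); cutoff
  choices should account for the cohort count.
* No p-value calibration is attached to either score; cutoffs are
  operating points, chosen by the user's precision/recall needs.
* No coordinate liftover: genome, annotation and peaks must share an
  assembly.
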