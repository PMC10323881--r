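# Joining PWM summaries with R-scores and applying the combined
# cutoffs; the end-to-end pipeline driver.

#' Percentile cutoff specification
#'
#' Marks a cutoff as "the p-th percentile of the observed score
#' distribution" rather than an absolute value. Percentiles are
#' resolved by [resolve_cutoff()] over the joined prediction table's
#' own values.
#'
#' @param p percentile in (0, 100), e.g. `pct(75)`.
#' @return a `percentile_spec` object.
#' @export
pct <- function(p) {
  if (!is_scalar_number(p) || p <= 0 || p >= 100)
    tfs_stop("tfscout_contract_error", "percentile must be in (0, 100)")
  structure(list(p = p), class = "percentile_spec")
}

#' Resolve a cutoff specification against observed values
#'
#' An absolute numeric cutoff passes through unchanged. A percentile
#' spec (see [pct()]) is resolved with the linear-interpolation
#' quantile definition (R's type 7, the default of
#' [stats::quantile()]): the p-th percentile of sorted values
#' `x_(1..n)` is `x_(k) + g (x_(k+1) - x_(k))` with
#' `h = (n - 1) p / 100 + 1`, `k = floor(h)`, `g = h - k`.
#'
#' @param values numeric vector of observed scores (non-empty for
#'   percentile mode).
#' @param spec a single number, or a `percentile_spec` from [pct()].
#' @return the resolved cutoff, a single number.
#' @examples
#' resolve_cutoff(c(1, 2, 3, 4), pct(75))  # 3.25
#' @export
resolve_cutoff <- function(values, spec) {
  if (inherits(spec, "percentile_spec")) {
    if (length(values) == 0L)
      tfs_stop("tfscout_contract_error",
               "cannot resolve a percentile cutoff over zero values")
    return(unname(stats::quantile(values, probs = spec$p / 100, type = 7,
                                  names = FALSE)))
  }
  if (!is_scalar_number(spec))
    tfs_stop("tfscout_contract_error", "cutoff must be a number or pct(p)")
  spec
}

#' Combined cutoff specification
#'
#' @param r_cutoff R-score cutoff: a number or [pct()] spec
#'   (default 0.7).
#' @param pwm_metric which PWM summary the cutoff applies to:
#'   `"k_max1"` (default), `"k_max3"` or `"k_total"`.
#' @param pwm_cutoff PWM-score cutoff: a number or [pct()] spec
#'   (default 8).
#' @param comparison `">"` (default, strict — a gene exactly at a
#'   cutoff fails) or `">="`.
#' @return a `cutoff_spec` object.
#' @export
cutoff_spec <- function(r_cutoff = 0.7, pwm_metric = c("k_max1", "k_max3", "k_total"),
                        pwm_cutoff = 8, comparison = c(">", ">=")) {
  structure(list(r_cutoff = r_cutoff,
                 pwm_metric = match.arg(pwm_metric),
                 pwm_cutoff = pwm_cutoff,
                 comparison = match.arg(comparison)),
            class = "cutoff_spec")
}

#' Predict target genes from joined PWM and correlation scores
#'
#' Inner-joins the PWM score table and the R-score table on `gene_id`
#' (genes present in only one input are excluded, mirroring the removal
#' of genes absent from the expression dataset; their counts are
#' reported in attributes) and flags each gene against the cutoffs.
#' Percentile cutoffs are resolved over the joined table's own values.
#'
#' @param score_summaries data.frame from [score_all_genes()].
#' @param r_score_records data.frame from [r_scores_all()].
#' @param cutoffs a `cutoff_spec` (default `cutoff_spec()`:
#'   R-score > 0.7 and k_max1 > 8).
#' @return data.frame with columns `gene_id`, `r_score`, `best_group`,
#'   `k_max1`, `k_max3`, `k_total`, `pass_r`, `pass_pwm`, `pass_all`,
#'   sorted by (`pass_all` desc, `r_score` desc, `gene_id` asc).
#'   Attributes: `n_only_pwm`, `n_only_r` (exclusion counts),
#'   `resolved_r_cutoff`, `resolved_pwm_cutoff`.
#' @export
predict_targets <- function(score_summaries, r_score_records,
                            cutoffs = cutoff_spec()) {
  stopifnot(inherits(cutoffs, "cutoff_spec"))
  shared <- intersect(score_summaries$gene_id, r_score_records$gene_id)
  n_only_pwm <- length(setdiff(score_summaries$gene_id, shared))
  n_only_r <- length(setdiff(r_score_records$gene_id, shared))
  if (length(shared) == 0L)
    warning("prediction join is empty: no gene has both a PWM summary and an R-score",
            call. = FALSE)
  pw <- score_summaries[match(shared, score_summaries$gene_id), , drop = FALSE]
  rr <- r_score_records[match(shared, r_score_records$gene_id), , drop = FALSE]
  df <- data.frame(gene_id = shared,
                   r_score = rr$r_score,
                   best_group = rr$best_group,
                   k_max1 = pw$k_max1, k_max3 = pw$k_max3,
                   k_total = pw$k_total, stringsAsFactors = FALSE)
  r_cut <- resolve_cutoff(df$r_score, cutoffs$r_cutoff)
  pwm_cut <- resolve_cutoff(df[[cutoffs$pwm_metric]], cutoffs$pwm_cutoff)
  cmp <- if (cutoffs$comparison == ">") `>` else `>=`
  df$pass_r <- cmp(df$r_score, r_cut)
  df$pass_pwm <- cmp(df[[cutoffs$pwm_metric]], pwm_cut)
  df$pass_all <- df$pass_r & df$pass_pwm
  df <- df[order(-df$pass_all, -df$r_score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_only_pwm") <- n_only_pwm
  attr(df, "n_only_r") <- n_only_r
  attr(df, "resolved_r_cutoff") <- r_cut
  attr(df, "resolved_pwm_cutoff") <- pwm_cut
  df
}

# wrap a pipeline stage so failures carry the stage name
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    tfs_stop("tfscout_stage_error", "[stage %s] %s", stage,
             conditionMessage(e))
  })
}

#' Run the full target-prediction pipeline
#'
#' End to end: PFM -> log-odds PWM -> promoter scan of every annotated
#' gene -> per-group correlation R-scores -> combined-cutoff
#' prediction. When a ChIP-seq reference is supplied, the final
#' prediction is also evaluated (sensitivity/specificity/precision/
#' P/C) and an ROC sweep over R-score cutoffs is run against the
#' expression gene universe.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param annotations annotation data.frame.
#' @param pfm a PFM object (single record of [read_jaspar_pfm()]).
#' @param expr an `expr_matrix` object.
#' @param tf_gene TF gene id in `expr`.
#' @param cutoffs a `cutoff_spec`.
#' @param upstream_length promoter length in bp (default 5000).
#' @param scan_reverse_strand scan both strands (default TRUE).
#' @param pseudocount,background passed to [pfm_to_pwm()].
#' @param absolute use absolute-value R-scores (default FALSE).
#' @param reference optional: a `reference_set` or character vector of
#'   reference target gene ids.
#' @return list with `predictions` (the [predict_targets()] table),
#'   `pwm_scores`, `r_scores`, `evaluation` (or NULL), `roc` (or NULL),
#'   `reference` (restricted to the expression universe, or NULL) and
#'   `manifest` (every parameter of the run).
#' @export
run_tf_pipeline <- function(genome, annotations, pfm, expr, tf_gene,
                            cutoffs = cutoff_spec(),
                            upstream_length = 5000L,
                            scan_reverse_strand = TRUE,
                            pseudocount = 0.8,
                            background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            absolute = FALSE,
                            reference = NULL) {
  pwm <- run_stage("pwm_conversion",
                   pfm_to_pwm(pfm, pseudocount = pseudocount,
                              background = background))
  pwm_scores <- run_stage("pwm_scoring",
                          score_all_genes(pwm, genome, annotations,
                                          upstream_length = upstream_length,
                                          scan_reverse_strand = scan_reverse_strand))
  r_scores <- run_stage("expression_correlation",
                        r_scores_all(expr, tf_gene, absolute = absolute))
  predictions <- run_stage("prediction",
                           predict_targets(pwm_scores, r_scores, cutoffs))
  evaluation <- roc <- ref <- NULL
  if (!is.null(reference)) {
    if (!inherits(reference, "reference_set"))
      reference <- reference_from_gene_ids(reference, tf_name = pfm$tf_name)
    A <- setdiff(rownames(expr$values), tf_gene)
    ref <- restrict_to_universe(reference, A)
    P <- predictions$gene_id[predictions$pass_all]
    evaluation <- run_stage("evaluation", evaluate_sets(A, ref$gene_ids, P))
    roc <- run_stage("evaluation",
                     roc_sweep(r_scores, ref$gene_ids, A,
                               comparison = cutoffs$comparison))
  }
  manifest <- list(
    tf_gene = tf_gene, tf_name = pfm$tf_name,
    n_genes_annotated = nrow(annotations),
    n_genes_expression = nrow(expr$values),
    upstream_length = upstream_length,
    scan_reverse_strand = scan_reverse_strand,
    pseudocount = pseudocount, background = unname(background),
    absolute_r = absolute,
    r_cutoff = attr(predictions, "resolved_r_cutoff"),
    pwm_metric = cutoffs$pwm_metric,
    pwm_cutoff = attr(predictions, "resolved_pwm_cutoff"),
    comparison = cutoffs$comparison,
    n_predicted = sum(predictions$pass_all)
  )
  list(predictions = predictions, pwm_scores = pwm_scores,
       r_scores = r_scores, evaluation = evaluation, roc = roc,
       reference = ref, manifest = manifest)
}

#' Write a run manifest as a two-column TSV
#'
#' @param manifest the `manifest` element of [run_tf_pipeline()]'s
#'   result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(key = names(manifest),
                   value = vapply(manifest, function(v)
                     paste(format(v, digits = 10), collapse = ","),
                     character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
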