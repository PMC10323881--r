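# Set-cardinality evaluation metrics against a ChIP-seq reference, and
# the ROC / precision sweeps over R-score cutoffs.
#
# With A the gene universe (all genes in the expression dataset), C the
# ChIP-seq reference targets and P the predicted targets:
#   sensitivity = |C n P| / |C|
#   specificity = (|A| - |C| - |P| + |C n P|) / (|A| - |C|)
#   precision   = |C n P| / |P|
#   P/C         = |P| / |C|   (relative number of predictions)

#' Evaluate a predicted set against a reference set
#'
#' Undefined ratios (e.g. precision when no gene is predicted) are
#' reported as `NA` and listed in `undefined` — never silently 0,
#' since the distinction drives the behaviour of the precision sweep
#' at extreme cutoffs.
#'
#' @param A character vector, the gene universe.
#' @param C character vector, reference targets; must be a subset of
#'   `A`.
#' @param P character vector, predicted targets; must be a subset of
#'   `A`.
#' @return list with `sensitivity`, `specificity`, `precision`,
#'   `p_over_c` (each numeric or `NA`), cardinalities `n_A`, `n_C`,
#'   `n_P`, `n_CP`, and `undefined` (character vector of metric names).
#' @examples
#' evaluate_sets(paste0("g", 1:100), paste0("g", 1:20), paste0("g", 16:25))
#' @export
evaluate_sets <- function(A, C, P) {
  A <- unique(as.character(A)); C <- unique(as.character(C))
  P <- unique(as.character(P))
  if (length(A) == 0L)
    tfs_stop("tfscout_contract_error", "universe A is empty")
  if (!all(C %in% A))
    tfs_stop("tfscout_contract_error", "C is not a subset of A")
  if (!all(P %in% A))
    tfs_stop("tfscout_contract_error", "P is not a subset of A")
  n_A <- length(A); n_C <- length(C); n_P <- length(P)
  n_CP <- length(intersect(C, P))
  undefined <- character(0)
  sens <- if (n_C > 0L) n_CP / n_C else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (n_A > n_C) (n_A - n_C - n_P + n_CP) / (n_A - n_C) else {
    undefined <- c(undefined, "specificity"); NA_real_ }
  prec <- if (n_P > 0L) n_CP / n_P else { undefined <- c(undefined, "precision"); NA_real_ }
  poc <- if (n_C > 0L) n_P / n_C else { undefined <- c(undefined, "p_over_c"); NA_real_ }
  list(sensitivity = sens, specificity = spec, precision = prec,
       p_over_c = poc, n_A = n_A, n_C = n_C, n_P = n_P, n_CP = n_CP,
       undefined = undefined)
}

# Resolve the cutoff grid for the sweeps: all distinct observed scores
# plus sentinels strictly below the minimum and above the maximum, so
# the curves reach both the everything-predicted and nothing-predicted
# regimes.
auto_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  c(u[1L] - 1, u, u[length(u)] + 1)
}

#' ROC sweep over R-score cutoffs
#'
#' For each cutoff `t` the predicted set is `P(t) = {genes with score
#' comparing favourably to t}` (strict `>` by default); the true
#' positive rate is the sensitivity and the false positive rate is
#' `1 - specificity` of [evaluate_sets()]. The AUC is computed by the
#' trapezoidal rule on the `(fpr, tpr)` points augmented with the
#' `(0,0)` and `(1,1)` endpoints. Genes of the universe without a
#' score are never predicted at any cutoff.
#'
#' @param r_scores data.frame with columns `gene_id`, `r_score` (e.g.
#'   from [r_scores_all()]).
#' @param C character vector, reference targets (subset of `A`,
#'   non-empty).
#' @param A character vector, the gene universe.
#' @param cutoffs numeric vector of cutoffs, or `"auto"` (default) for
#'   all distinct observed scores plus sentinels.
#' @param comparison `">"` (default, a gene exactly at the cutoff is
#'   excluded) or `">="`.
#' @return a `roc_curve` object: list with `curve` (data.frame
#'   `cutoff`, `fpr`, `tpr`, sorted by cutoff) and `auc`.
#' @export
roc_sweep <- function(r_scores, C, A, cutoffs = "auto", comparison = c(">", ">=")) {
  comparison <- match.arg(comparison)
  C <- unique(as.character(C)); A <- unique(as.character(A))
  if (length(C) == 0L)
    tfs_stop("tfscout_undefined_roc", "reference set C is empty")
  if (!all(C %in% A))
    tfs_stop("tfscout_contract_error", "C is not a subset of A")
  if (!all(r_scores$gene_id %in% A))
    tfs_stop("tfscout_contract_error", "scored gene(s) outside universe A")
  s <- r_scores$r_score
  ids <- r_scores$gene_id
  if (identical(cutoffs, "auto")) cutoffs <- auto_cutoffs(s)
  cutoffs <- sort(as.numeric(cutoffs))
  cmp <- if (comparison == ">") `>` else `>=`
  pos <- ids %in% C
  n_C <- length(C); n_neg <- length(A) - n_C
  tpr <- fpr <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    sel <- cmp(s, cutoffs[i])
    tpr[i] <- sum(sel & pos) / n_C
    fpr[i] <- if (n_neg > 0L) sum(sel & !pos) / n_neg else NA_real_
  }
  curve <- data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr)
  pts <- unique(rbind(data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                      curve[, c("fpr", "tpr")]))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC over %d cutoff(s); AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Precision and relative prediction count across cutoffs
#'
#' For each cutoff, the precision `|C n P(t)| / |P(t)|` and the
#' relative number of predictions `P/C = |P(t)| / |C|`. Rows where no
#' gene is predicted have `NA` precision (flagged, not zero).
#'
#' @inheritParams roc_sweep
#' @return data.frame with columns `cutoff`, `n_P`, `precision`,
#'   `p_over_c`.
#' @export
precision_sweep <- function(r_scores, C, A, cutoffs = "auto",
                            comparison = c(">", ">=")) {
  comparison <- match.arg(comparison)
  C <- unique(as.character(C)); A <- unique(as.character(A))
  if (length(C) == 0L)
    tfs_stop("tfscout_undefined_roc", "reference set C is empty")
  if (!all(C %in% A))
    tfs_stop("tfscout_contract_error", "C is not a subset of A")
  if (!all(r_scores$gene_id %in% A))
    tfs_stop("tfscout_contract_error", "scored gene(s) outside universe A")
  s <- r_scores$r_score
  pos <- r_scores$gene_id %in% C
  if (identical(cutoffs, "auto")) cutoffs <- auto_cutoffs(s)
  cutoffs <- sort(as.numeric(cutoffs))
  cmp <- if (comparison == ">") `>` else `>=`
  n_P <- vapply(cutoffs, function(t) sum(cmp(s, t)), numeric(1))
  n_CP <- vapply(cutoffs, function(t) sum(cmp(s, t) & pos), numeric(1))
  data.frame(cutoff = cutoffs, n_P = as.integer(n_P),
             precision = ifelse(n_P > 0, n_CP / n_P, NA_real_),
             p_over_c = n_P / length(C))
}
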