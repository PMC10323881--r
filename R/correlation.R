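# Per-group Pearson correlation between a TF and candidate genes, and
# the R-score: the maximum across sample groups (cancer types).

MIN_GROUP_SIZE <- 3L

#' Pearson correlation with explicit failure modes
#'
#' Standard product-moment correlation, clamped to `[-1, 1]` against
#' floating-point rounding. Fewer than 3 paired observations or zero
#' variance in either vector raise classed errors
#' (`tfscout_insufficient_samples`, `tfscout_zero_variance`) that
#' [group_correlations()] converts into reason codes.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    tfs_stop("tfscout_contract_error", "x and y must have equal length")
  if (length(x) < MIN_GROUP_SIZE)
    tfs_stop("tfscout_insufficient_samples",
             "need >= %d paired observations, got %d", MIN_GROUP_SIZE, length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    tfs_stop("tfscout_zero_variance", "correlation undefined: zero variance")
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Per-group correlations between a TF and one candidate gene
#'
#' Splits samples by group and computes the Pearson correlation of the
#' two genes' expression in each group. Groups where the correlation is
#' undefined are kept with `r = NA` and a reason code
#' (`"insufficient_samples"` for < 3 samples, `"zero_variance"`).
#'
#' @param expr an `expr_matrix` object.
#' @param tf_gene,target_gene gene ids present in `expr`.
#' @return data.frame with columns `group`, `r`, `reason` (`NA` when
#'   defined), one row per group, sorted by group label.
#' @export
group_correlations <- function(expr, tf_gene, target_gene) {
  stopifnot(inherits(expr, "expr_matrix"))
  for (g in c(tf_gene, target_gene))
    if (!g %in% rownames(expr$values))
      tfs_stop("tfscout_lookup_error", "gene '%s' not in expression matrix", g)
  groups <- sort(unique(expr$groups))
  r <- rep(NA_real_, length(groups))
  reason <- rep(NA_character_, length(groups))
  for (i in seq_along(groups)) {
    idx <- which(expr$groups == groups[i])
    res <- tryCatch(
      pearson_r(expr$values[tf_gene, idx], expr$values[target_gene, idx]),
      tfscout_insufficient_samples = function(e) "insufficient_samples",
      tfscout_zero_variance = function(e) "zero_variance")
    if (is.character(res)) reason[i] <- res else r[i] <- res
  }
  data.frame(group = groups, r = r, reason = reason, stringsAsFactors = FALSE)
}

#' R-score of one candidate gene
#'
#' The R-score is the maximum Pearson correlation between the TF and
#' the candidate across sample groups. By default the signed maximum;
#' with `absolute = TRUE` the maximum of `|r|` is reported (the signed
#' per-group value is retained in `per_group_r`), which surfaces
#' strongly anticorrelated candidates of repressive TFs. Ties are
#' broken by lexicographic group label.
#'
#' @param expr an `expr_matrix` object.
#' @param tf_gene,target_gene gene ids present in `expr`.
#' @param absolute maximise `|r|` instead of signed `r`.
#' @return list with `gene_id`, `r_score`, `best_group`, `per_group_r`
#'   (the [group_correlations()] data.frame), `n_groups_evaluated`.
#' @export
r_score <- function(expr, tf_gene, target_gene, absolute = FALSE) {
  pg <- group_correlations(expr, tf_gene, target_gene)
  defined <- which(!is.na(pg$r))
  if (length(defined) == 0L)
    tfs_stop("tfscout_no_score", "no group yields a defined correlation for %s",
             target_gene)
  val <- if (absolute) abs(pg$r[defined]) else pg$r[defined]
  best <- defined[order(-val, pg$group[defined])][1L]
  list(gene_id = target_gene,
       r_score = if (absolute) abs(pg$r[best]) else pg$r[best],
       best_group = pg$group[best],
       per_group_r = pg,
       n_groups_evaluated = length(defined))
}

#' R-scores of many candidate genes
#'
#' Vectorised per-group correlation of the TF against every candidate,
#' reduced to one R-score per gene. The TF itself is excluded from the
#' candidate list (its self-correlation of 1 is degenerate).
#' Candidates with no defined group in any cancer type are skipped and
#' reported in the `skipped` attribute.
#'
#' @param expr an `expr_matrix` object.
#' @param tf_gene TF gene id, must be present in `expr`.
#' @param candidate_genes gene ids to score; default all genes in
#'   `expr` except the TF.
#' @param absolute maximise `|r|` instead of signed `r`.
#' @return data.frame (`gene_id`, `r_score`, `best_group`,
#'   `n_groups_evaluated`) sorted by `r_score` descending, ties by
#'   `gene_id`; attribute `skipped` is a character vector of candidates
#'   with no defined group.
#' @export
r_scores_all <- function(expr, tf_gene,
                         candidate_genes = setdiff(rownames(expr$values), tf_gene),
                         absolute = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!tf_gene %in% rownames(expr$values))
    tfs_stop("tfscout_lookup_error", "TF gene '%s' not in expression matrix",
             tf_gene)
  candidate_genes <- setdiff(unique(candidate_genes), tf_gene)
  missing <- setdiff(candidate_genes, rownames(expr$values))
  if (length(missing))
    tfs_stop("tfscout_lookup_error", "candidate gene(s) not in expression matrix: %s",
             paste(head(missing, 5L), collapse = ", "))
  groups <- sort(unique(expr$groups))
  # groups x candidates matrix of per-group correlations (NA = undefined)
  rmat <- matrix(NA_real_, nrow = length(groups), ncol = length(candidate_genes),
                 dimnames = list(groups, candidate_genes))
  for (i in seq_along(groups)) {
    idx <- which(expr$groups == groups[i])
    if (length(idx) < MIN_GROUP_SIZE) next
    tf_x <- expr$values[tf_gene, idx]
    if (stats::sd(tf_x) == 0) next
    y <- t(expr$values[candidate_genes, idx, drop = FALSE])
    rmat[i, ] <- suppressWarnings(as.numeric(stats::cor(tf_x, y)))
  }
  rmat[] <- pmax(-1, pmin(1, rmat))
  key <- if (absolute) abs(rmat) else rmat
  n_def <- colSums(!is.na(key))
  scored <- which(n_def > 0L)
  # per candidate: row index of the best defined group (groups are sorted,
  # so which.max's first-hit rule is the lexicographic tie-break)
  best_i <- vapply(scored, function(j) which.max(key[, j]), integer(1))
  out <- data.frame(
    gene_id = candidate_genes[scored],
    r_score = key[cbind(best_i, scored)],
    best_group = groups[best_i],
    n_groups_evaluated = n_def[scored],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$r_score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- candidate_genes[n_def == 0L]
  out
}
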