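# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use a different computational route than the
# package code they check.

# Brute-force promoter scorer: enumerate every window by substring,
# skip windows containing N, score each base with an explicit loop.
brute_score_promoter <- function(mat, sequence, both_strands = TRUE) {
  row_of <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  n <- ncol(mat)
  one_strand <- function(s) {
    L <- nchar(s)
    if (L < n) return(list(scores = numeric(0), skipped = 0L))
    scores <- c(); skipped <- 0L
    for (start in seq_len(L - n + 1L)) {
      w <- substr(s, start, start + n - 1L)
      chars <- strsplit(w, "")[[1L]]
      if (any(!chars %in% names(row_of))) { skipped <- skipped + 1L; next }
      k <- 0
      for (i in seq_len(n)) k <- k + unname(mat[row_of[[chars[i]]], i])
      scores <- c(scores, k)
    }
    list(scores = scores, skipped = skipped)
  }
  fw <- one_strand(sequence)
  rv <- if (both_strands) one_strand(brute_revcomp(sequence)) else
    list(scores = numeric(0), skipped = 0L)
  scores <- c(fw$scores, rv$scores)
  if (length(scores) == 0L)
    return(list(k_max1 = 0, k_max3 = 0, k_total = 0, n_windows = 0L,
                n_skipped = fw$skipped + rv$skipped))
  srt <- sort(scores, decreasing = TRUE)
  list(k_max1 = srt[1L],
       k_max3 = sum(srt[seq_len(min(3L, length(srt)))]),
       k_total = sum(scores),
       n_windows = length(scores),
       n_skipped = fw$skipped + rv$skipped)
}

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

random_pwm_matrix <- function(n, lo = -3, hi = 3) {
  matrix(round(runif(4L * n, lo, hi), 3), nrow = 4L,
         dimnames = list(c("A", "T", "C", "G"), NULL))
}

random_dna <- function(len, p_n = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# Two-pass closed-form Pearson correlation (sum of products of
# deviations), independent of stats::cor.
closed_form_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Mann-Whitney rank statistic P(s+ > s-) + 0.5 P(s+ = s-): the
# probabilistic definition of the AUC, computed by pairwise comparison.
mann_whitney_auc <- function(scores, is_positive) {
  sp <- scores[is_positive]; sn <- scores[!is_positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# A tiny deterministic expression matrix: values given per group as a
# list of gene -> numeric vectors.
make_expr <- function(per_group_values) {
  groups <- character(0); samples <- character(0)
  mats <- list()
  for (g in names(per_group_values)) {
    block <- do.call(rbind, per_group_values[[g]])
    cols <- sprintf("%s_s%d", g, seq_len(ncol(block)))
    colnames(block) <- cols
    mats[[g]] <- block
    samples <- c(samples, cols)
    groups <- c(groups, rep(g, ncol(block)))
  }
  values <- do.call(cbind, mats)
  rownames(values) <- names(per_group_values[[1L]])
  names(groups) <- samples
  new_expr_matrix(values, groups)
}
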