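# Promoter extraction and sliding-window PWM scoring.
#
# Base-to-row convention of the scoring matrix: row 1 = A, row 2 = T,
# row 3 = C, row 4 = G. pfm_to_pwm() emits matrices in this order.
PWM_ROW_ORDER <- c("A", "T", "C", "G")

#' Extract the promoter sequence of a gene
#'
#' Returns the `upstream_length` bases immediately upstream of the TSS,
#' written 5'->3' on the gene's coding orientation: for a `+` gene the
#' forward-strand slice `[tss - L, tss)`, for a `-` gene the
#' reverse complement of `[tss + 1, tss + 1 + L)`. If the chromosome
#' end clips the window the available bases are returned and
#' `truncated` is set.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param gene one-row annotation (list or data.frame row with
#'   `gene_id`, `chrom`, `tss`, `strand`).
#' @param upstream_length promoter length L in bp (default 5000).
#' @return list with `gene_id`, `sequence`, `requested_length`,
#'   `actual_length`, `truncated`.
#' @examples
#' g <- c(c1 = "ACGTACGTAC")
#' extract_promoter(g, list(gene_id = "g", chrom = "c1", tss = 8, strand = "+"), 4)
#' @export
extract_promoter <- function(genome, gene, upstream_length = 5000L) {
  stopifnot(upstream_length >= 1L)
  chrom <- as.character(gene$chrom)
  if (!chrom %in% names(genome))
    tfs_stop("tfscout_lookup_error", "unknown chromosome '%s' for gene %s",
             chrom, gene$gene_id)
  seq <- genome[[chrom]]
  len <- nchar(seq)
  tss <- as.integer(gene$tss)
  if (is.na(tss) || tss < 0L || tss >= len)
    tfs_stop("tfscout_lookup_error",
             "tss %s outside chromosome '%s' (length %d) for gene %s",
             gene$tss, chrom, len, gene$gene_id)
  L <- as.integer(upstream_length)
  if (gene$strand == "+") {
    from <- max(0L, tss - L)           # 0-based [from, tss)
    s <- substr(seq, from + 1L, tss)   # may be empty when tss == 0
    truncated <- (tss - L) < 0L
  } else if (gene$strand == "-") {
    to <- min(len, tss + 1L + L)       # 0-based [tss + 1, to)
    s <- revcomp(substr(seq, tss + 2L, to))
    truncated <- (tss + 1L + L) > len
  } else {
    tfs_stop("tfscout_contract_error", "strand must be '+' or '-', got '%s'",
             gene$strand)
  }
  list(gene_id = as.character(gene$gene_id), sequence = s,
       requested_length = L, actual_length = nchar(s), truncated = truncated)
}

#' Segment a sequence into sliding windows
#'
#' All contiguous substrings of length `n`, stride 1, left to right.
#' A sequence shorter than `n` yields no windows.
#'
#' @param sequence a single DNA string.
#' @param n window (motif) length, >= 1.
#' @return character vector of windows (possibly empty).
#' @examples
#' segment_sequence("AATTCCGG", 4)
#' @export
segment_sequence <- function(sequence, n) {
  stopifnot(is.character(sequence), length(sequence) == 1L, n >= 1L)
  L <- nchar(sequence)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1L)
  substring(sequence, starts, starts + n - 1L)
}

#' Score one window against a PWM
#'
#' The window score is the sum of the matrix entries selected by the
#' window's bases: `k = sum_i a(m(x_i), i)` with row mapping A->1,
#' T->2, C->3, G->4. The window must be exactly the motif length and
#' free of `N` (callers skip N-containing windows).
#'
#' @param pwm a PWM object from [pfm_to_pwm()] (or a bare 4 x n matrix
#'   with rows in A,T,C,G order).
#' @param window a string over `{A,C,G,T}` of length `ncol`.
#' @return the window score, a single number.
#' @export
score_window <- function(pwm, window) {
  mat <- pwm_matrix(pwm)
  n <- ncol(mat)
  if (nchar(window) != n)
    tfs_stop("tfscout_contract_error",
             "window length %d does not match motif length %d",
             nchar(window), n)
  codes <- match(strsplit(window, "")[[1L]], PWM_ROW_ORDER)
  if (anyNA(codes))
    tfs_stop("tfscout_contract_error",
             "window contains a base outside {A,C,G,T}: %s", window)
  sum(mat[cbind(codes, seq_len(n))])
}

pwm_matrix <- function(pwm) {
  mat <- if (inherits(pwm, "tf_pwm")) pwm$matrix else pwm
  stopifnot(is.matrix(mat), nrow(mat) == 4L, ncol(mat) >= 1L,
            all(is.finite(mat)))
  mat
}

# Vectorised scores of every stride-1 window of `sequence`; windows
# containing N come back NA.
window_scores <- function(mat, sequence) {
  codes <- match(strsplit(sequence, "")[[1L]], PWM_ROW_ORDER)
  n <- ncol(mat)
  nw <- length(codes) - n + 1L
  if (nw < 1L) return(numeric(0))
  s <- numeric(nw)
  for (j in seq_len(n)) {
    col <- unname(mat[, j])
    s <- s + col[codes[j:(j + nw - 1L)]]  # NA propagates for N windows
  }
  s
}

#' Score a promoter: k_max1, k_max3, k_total
#'
#' Scores every N-free window of the promoter (and, by default, of its
#' reverse complement, pooling both strands into one score list) and
#' summarises: `k_max1` is the best window score, `k_max3` the sum of
#' the three best (or of all windows when fewer than three exist),
#' `k_total` the sum over all windows. A promoter yielding no scorable
#' window gets all three summaries 0, `n_windows = 0` and
#' `no_windows = TRUE` so callers can filter rather than lose the gene.
#'
#' @param pwm a PWM object or 4 x n matrix (rows A,T,C,G).
#' @param promoter a promoter from [extract_promoter()], or a bare
#'   sequence string.
#' @param scan_reverse_strand also scan the reverse complement
#'   (default TRUE).
#' @return list with `gene_id`, `k_max1`, `k_max3`, `k_total`,
#'   `n_windows`, `n_skipped_windows`, `no_windows`.
#' @export
score_promoter <- function(pwm, promoter, scan_reverse_strand = TRUE) {
  mat <- pwm_matrix(pwm)
  if (is.character(promoter))
    promoter <- list(gene_id = NA_character_, sequence = promoter)
  seq <- promoter$sequence
  scores <- window_scores(mat, seq)
  if (isTRUE(scan_reverse_strand))
    scores <- c(scores, window_scores(mat, revcomp(seq)))
  skipped <- sum(is.na(scores))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L)
    return(list(gene_id = promoter$gene_id, k_max1 = 0, k_max3 = 0,
                k_total = 0, n_windows = 0L, n_skipped_windows = skipped,
                no_windows = TRUE))
  top <- sort(scores, decreasing = TRUE)
  list(gene_id = promoter$gene_id,
       k_max1 = top[1L],
       k_max3 = sum(top[seq_len(min(3L, length(top)))]),
       k_total = sum(scores),
       n_windows = length(scores),
       n_skipped_windows = skipped,
       no_windows = FALSE)
}

#' Score every annotated gene's promoter
#'
#' Runs [extract_promoter()] + [score_promoter()] over an annotation
#' table. Genes whose promoter cannot be extracted (unknown chromosome,
#' TSS out of range) are collected in the `failures` attribute rather
#' than dropped silently.
#'
#' @param pwm a PWM object.
#' @param genome named character vector of chromosome sequences.
#' @param annotations annotation data.frame from
#'   [read_gene_annotation()].
#' @param upstream_length promoter length in bp (default 5000).
#' @param scan_reverse_strand also scan the reverse complement
#'   (default TRUE).
#' @return data.frame with one row per successfully scored gene
#'   (`gene_id`, `k_max1`, `k_max3`, `k_total`, `n_windows`,
#'   `n_skipped_windows`, `no_windows`), in annotation order; attribute
#'   `failures` is a data.frame (`gene_id`, `message`) of per-gene
#'   extraction errors.
#' @export
score_all_genes <- function(pwm, genome, annotations, upstream_length = 5000L,
                            scan_reverse_strand = TRUE) {
  stopifnot(nrow(annotations) >= 1L)
  mat <- pwm_matrix(pwm)
  rows <- vector("list", nrow(annotations))
  fail_id <- character(0); fail_msg <- character(0)
  for (i in seq_len(nrow(annotations))) {
    gene <- annotations[i, ]
    prom <- tryCatch(extract_promoter(genome, gene, upstream_length),
                     tfscout_error = function(e) e)
    if (inherits(prom, "condition")) {
      fail_id <- c(fail_id, gene$gene_id)
      fail_msg <- c(fail_msg, conditionMessage(prom))
      next
    }
    rows[[i]] <- score_promoter(mat, prom, scan_reverse_strand)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) {
    data.frame(
      gene_id = vapply(rows, `[[`, character(1), "gene_id"),
      k_max1 = vapply(rows, `[[`, numeric(1), "k_max1"),
      k_max3 = vapply(rows, `[[`, numeric(1), "k_max3"),
      k_total = vapply(rows, `[[`, numeric(1), "k_total"),
      n_windows = vapply(rows, `[[`, integer(1), "n_windows"),
      n_skipped_windows = vapply(rows, function(r) as.integer(r$n_skipped_windows), integer(1)),
      no_windows = vapply(rows, `[[`, logical(1), "no_windows"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(gene_id = character(0), k_max1 = numeric(0),
               k_max3 = numeric(0), k_total = numeric(0),
               n_windows = integer(0), n_skipped_windows = integer(0),
               no_windows = logical(0), stringsAsFactors = FALSE)
  }
  attr(out, "failures") <- data.frame(gene_id = fail_id, message = fail_msg,
                                      stringsAsFactors = FALSE)
  out
}
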