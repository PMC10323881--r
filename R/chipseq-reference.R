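# Reference target sets from ChIP-seq peaks: enrichment filtering and
# promoter-window assignment of peaks to genes.

#' Filter peaks by fold enrichment and read support
#'
#' Keeps peaks with `fold_change` strictly greater than
#' `min_fold_change` ("more than 1.5-fold") and `read_count` of at
#' least `min_reads` ("at least 10 distinct reads"). Idempotent and
#' order-preserving.
#'
#' @param peaks peak data.frame from [read_peaks()].
#' @param min_fold_change enrichment threshold, strict (default 1.5).
#' @param min_reads read-count threshold, inclusive (default 10).
#' @return the passing subset of `peaks`, in input order.
#' @export
filter_peaks <- function(peaks, min_fold_change = 1.5, min_reads = 10L) {
  stopifnot(is.data.frame(peaks))
  keep <- peaks$fold_change > min_fold_change & peaks$read_count >= min_reads
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign peaks to genes by promoter-window overlap
#'
#' A gene enters the reference set iff at least one peak (already
#' filtered by the caller, typically via [filter_peaks()]) overlaps its
#' strand-aware promoter window: for a `+` gene the interval
#' `[tss - window_upstream, tss + window_downstream)`, mirrored for a
#' `-` gene (`upstream` extends to higher coordinates). Peaks that
#' overlap no window are counted as intergenic; peaks on chromosomes
#' absent from the annotation are reported in `skipped_chroms`.
#'
#' This promoter-proximity rule is a deliberate, configurable
#' simplification of full nearest-feature peak annotation; callers with
#' an externally annotated gene list can skip it and build the set with
#' [reference_from_gene_ids()].
#'
#' @param peaks peak data.frame (0-based half-open coordinates).
#' @param annotations annotation data.frame.
#' @param window_upstream bp upstream of the TSS included in the
#'   promoter window (default 5000).
#' @param window_downstream bp downstream (default 1000).
#' @param tf_name label carried into the result.
#' @return a `reference_set` object: list with `tf_name`, `gene_ids`
#'   (character, sorted), `n_peaks_input`, `n_peaks_passing` (peaks
#'   hitting >= 1 promoter window), `n_intergenic`, `skipped_chroms`.
#' @export
assign_peaks_to_genes <- function(peaks, annotations,
                                  window_upstream = 5000L,
                                  window_downstream = 1000L,
                                  tf_name = "TF") {
  stopifnot(nrow(annotations) >= 1L, window_upstream >= 0L,
            window_downstream >= 0L)
  plus <- annotations$strand == "+"
  win_start <- ifelse(plus,
                      annotations$tss - window_upstream,
                      annotations$tss - window_downstream + 1L)
  win_end <- ifelse(plus,
                    annotations$tss + window_downstream,
                    annotations$tss + window_upstream + 1L)
  win_start <- pmax(0L, as.integer(win_start))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = win_start + 1L, end = win_end))
  known <- peaks$chrom %in% as.character(unique(annotations$chrom))
  skipped_chroms <- unique(peaks$chrom[!known])
  pk <- peaks[known, , drop = FALSE]
  hit_genes <- character(0)
  n_hit_peaks <- 0L
  if (nrow(pk) > 0L) {
    peak_gr <- GenomicRanges::GRanges(
      seqnames = pk$chrom,
      ranges = IRanges::IRanges(start = pk$start + 1L, end = pk$end))
    ov <- GenomicRanges::findOverlaps(peak_gr, gene_gr)
    hit_genes <- annotations$gene_id[unique(S4Vectors::subjectHits(ov))]
    n_hit_peaks <- length(unique(S4Vectors::queryHits(ov)))
  }
  structure(list(
    tf_name = tf_name,
    gene_ids = sort(unique(hit_genes)),
    n_peaks_input = nrow(peaks),
    n_peaks_passing = n_hit_peaks,
    n_intergenic = nrow(pk) - n_hit_peaks,
    skipped_chroms = skipped_chroms
  ), class = "reference_set")
}

#' Build a reference set from a plain gene-id list
#'
#' For users who already have an externally annotated ChIP-seq target
#' list (e.g. from a dedicated peak-annotation package).
#'
#' @param gene_ids character vector of target gene ids.
#' @param tf_name label carried into the result.
#' @return a `reference_set` object.
#' @export
reference_from_gene_ids <- function(gene_ids, tf_name = "TF") {
  structure(list(tf_name = tf_name, gene_ids = sort(unique(gene_ids)),
                 n_peaks_input = NA_integer_, n_peaks_passing = NA_integer_,
                 n_intergenic = NA_integer_, skipped_chroms = character(0)),
            class = "reference_set")
}

#' Restrict a reference set to a gene universe
#'
#' Genes absent from the expression dataset (or any other universe the
#' evaluation is run against) are removed from the reference set.
#'
#' @param reference a `reference_set` object.
#' @param universe_gene_ids character vector defining the universe.
#' @return the restricted `reference_set`.
#' @export
restrict_to_universe <- function(reference, universe_gene_ids) {
  stopifnot(inherits(reference, "reference_set"))
  reference$gene_ids <- sort(intersect(reference$gene_ids, universe_gene_ids))
  reference
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("ChIP-seq reference set for %s: %d gene(s)\n",
              x$tf_name, length(x$gene_ids)))
  if (!is.na(x$n_peaks_input))
    cat(sprintf("  peaks: %d in, %d assigned, %d intergenic\n",
                x$n_peaks_input, x$n_peaks_passing, x$n_intergenic))
  invisible(x)
}
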