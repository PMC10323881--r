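#' Read a genome from a FASTA file
#'
#' Loads every record of a FASTA file into a named character vector of
#' uppercase sequences. The name of each entry is the first
#' whitespace-delimited token of its header. Characters outside
#' `{A,C,G,T,N}` (e.g. IUPAC ambiguity codes) are normalised to `N`;
#' when any substitution happens a warning reports how many.
#'
#' All genomic coordinates in this package are 0-based half-open.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per record.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) tfs_stop("tfscout_format_error",
                                 "not a readable FASTA file: %s (%s)",
                                 path, conditionMessage(e))
  )
  if (length(seqs) == 0L)
    tfs_stop("tfscout_format_error", "FASTA file contains no records: %s", path)
  nm <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    tfs_stop("tfscout_format_error", "duplicate FASTA record name: %s",
             nm[duplicated(nm)][1L])
  out <- toupper(as.character(seqs))
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", out), function(m)
    if (m[1L] == -1L) 0L else length(m), integer(1)))
  if (n_bad > 0L) {
    out <- gsub("[^ACGTN]", "N", out)
    warning(sprintf("%d non-ACGTN character(s) normalised to N", n_bad),
            call. = FALSE)
  }
  if (any(nchar(out) < 1L))
    tfs_stop("tfscout_format_error", "empty sequence for record: %s",
             nm[nchar(out) < 1L][1L])
  names(out) <- nm
  out
}

#' Read a gene annotation table
#'
#' Tab-separated columns `gene_id`, `chrom`, `tss`, `strand`; lines
#' starting with `#` are comments. The TSS is a 0-based genomic
#' position; strand is `+` or `-`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (integer),
#'   `strand`, in file order.
#' @export
read_gene_annotation <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_annotation())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_ncol <- which(lengths(parts) < 4L)
  if (length(bad_ncol))
    tfs_stop("tfscout_format_error",
             "line %d: expected 4 tab-separated fields", line_no[bad_ncol[1L]])
  df <- data.frame(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    chrom   = vapply(parts, `[[`, character(1), 2L),
    tss     = suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L))),
    strand  = vapply(parts, `[[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand))
    tfs_stop("tfscout_format_error", "line %d: strand must be '+' or '-', got '%s'",
             line_no[bad_strand[1L]], df$strand[bad_strand[1L]])
  bad_tss <- which(is.na(df$tss) | df$tss < 0L)
  if (length(bad_tss))
    tfs_stop("tfscout_format_error", "line %d: tss must be a non-negative integer",
             line_no[bad_tss[1L]])
  if (anyDuplicated(df$gene_id))
    tfs_stop("tfscout_format_error", "duplicate gene_id: %s",
             df$gene_id[duplicated(df$gene_id)][1L])
  df
}

empty_annotation <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             tss = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016+ dialect: a header line `>ID NAME` followed by
#' four rows `A [ 3 0 ... ]`, `C [...]`, `G [...]`, `T [...]`. A file
#' may hold several concatenated records.
#'
#' @param path path to the PFM file.
#' @return list of PFM objects; each is a list with `tf_name` (string)
#'   and `counts`, a 4 x n integer matrix with rownames `A,C,G,T`.
#' @export
read_jaspar_pfm <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L)
    tfs_stop("tfscout_format_error", "no '>' header found in %s", path)
  ends <- c(headers[-1L] - 1L, length(lines))
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    block <- lines[headers[i]:ends[i]]
    hdr <- sub("^>", "", block[1L])
    toks <- strsplit(hdr, "[[:space:]]+")[[1L]]
    tf_name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- block[-1L]
    counts <- vector("list", 4L)
    names(counts) <- c("A", "C", "G", "T")
    for (base in c("A", "C", "G", "T")) {
      ln <- grep(sprintf("^%s[[:space:]\\[]", base), body, value = TRUE)
      if (length(ln) != 1L)
        tfs_stop("tfscout_format_error",
                 "record '%s': expected exactly one '%s' line", tf_name, base)
      stripped <- sub("^[ACGT]", "", ln)
      nums <- regmatches(stripped, gregexpr("[0-9]+", stripped))[[1L]]
      counts[[base]] <- as.integer(nums)
    }
    n <- unique(lengths(counts))
    if (length(n) != 1L)
      tfs_stop("tfscout_format_error",
               "record '%s': ragged rows (column counts %s)", tf_name,
               paste(lengths(counts), collapse = ","))
    if (n < 1L)
      tfs_stop("tfscout_format_error", "record '%s': empty matrix", tf_name)
    m <- do.call(rbind, counts)
    if (any(colSums(m) < 1L))
      tfs_stop("tfscout_format_error",
               "record '%s': a column sums to zero", tf_name)
    out[[i]] <- list(tf_name = tf_name, counts = m)
  }
  out
}

#' Write a PFM in JASPAR text format
#'
#' Inverse of [read_jaspar_pfm()] for a single record.
#'
#' @param pfm a PFM object (`tf_name`, 4 x n `counts` matrix).
#' @param path output path.
#' @param id matrix identifier for the header line.
#' @return invisibly, `path`.
#' @export
write_jaspar_pfm <- function(pfm, path, id = pfm$tf_name) {
  m <- pfm$counts
  lines <- c(sprintf(">%s %s", id, pfm$tf_name),
             vapply(c("A", "C", "G", "T"), function(b)
               sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Each entry is the log2 odds of observing base `b` at motif position
#' `j` under the motif versus under the background:
#' \deqn{a_{bj} = \log_2 \frac{(c_{bj} + p \cdot q_b) / (N_j + p)}{q_b}}
#' where \eqn{c_{bj}} is the count, \eqn{N_j} the column sum, \eqn{p}
#' the pseudocount and \eqn{q_b} the background probability of base `b`.
#'
#' The returned matrix uses row order `A,T,C,G` (the scoring
#' convention of [score_window()]), not the `A,C,G,T` order of JASPAR
#' files.
#'
#' @param pfm a PFM object from [read_jaspar_pfm()].
#' @param pseudocount positive smoothing mass, split across bases in
#'   proportion to the background. Default 0.8.
#' @param background length-4 probability vector in `A,C,G,T` order
#'   (named or unnamed); must sum to 1. Default uniform.
#' @return a PWM object: list with `tf_name` and `matrix`, a 4 x n
#'   numeric matrix with rownames `A,T,C,G`.
#' @examples
#' pfm <- list(tf_name = "TF", counts = matrix(c(3, 0, 0, 1), 4, 1,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' pfm_to_pwm(pfm)$matrix
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(is.list(pfm), is.matrix(pfm$counts), nrow(pfm$counts) == 4L)
  if (!is_scalar_number(pseudocount) || pseudocount <= 0)
    tfs_stop("tfscout_contract_error", "pseudocount must be a positive number")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    tfs_stop("tfscout_contract_error",
             "background must be 4 positive probabilities summing to 1")
  bg <- as.numeric(background)
  names(bg) <- c("A", "C", "G", "T")
  cnt <- pfm$counts
  rownames(cnt) <- c("A", "C", "G", "T")
  csum <- colSums(cnt)
  mat <- log2(sweep(
    sweep(cnt + pseudocount * bg, 2L, csum + pseudocount, "/"),
    1L, bg, "/"))
  structure(list(tf_name = pfm$tf_name,
                 matrix = mat[c("A", "T", "C", "G"), , drop = FALSE]),
            class = "tf_pwm")
}

#' @export
print.tf_pwm <- function(x, ...) {
  cat(sprintf("PWM for %s (%d positions, log2-odds)\n",
              x$tf_name, ncol(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Read an expression matrix with sample groups
#'
#' `values_path` is a TSV whose first column is `gene_id` and whose
#' remaining columns are samples (header row required). `groups_path`
#' is a two-column TSV `sample_id`, `group` (e.g. a cancer-type code).
#' Every sample column must have a group; missing values in the
#' expression table are rejected so downstream correlations are
#' unambiguous.
#'
#' @param values_path path to the expression TSV.
#' @param groups_path path to the sample-to-group TSV.
#' @return an `expr_matrix` object: list with `values` (genes x samples
#'   numeric matrix, dimnames set) and `groups` (named character vector,
#'   sample_id -> group).
#' @export
read_expression_matrix <- function(values_path, groups_path) {
  stopifnot(file.exists(values_path), file.exists(groups_path))
  tab <- read.delim(values_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    tfs_stop("tfscout_format_error", "expression table needs >= 1 sample column")
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids))
    tfs_stop("tfscout_format_error", "duplicate gene_id in expression table: %s",
             gene_ids[duplicated(gene_ids)][1L])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  if (anyNA(values))
    tfs_stop("tfscout_format_error", "expression table contains missing values")
  gr <- read.delim(groups_path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  # tolerate a header row naming the columns
  if (nrow(gr) && identical(tolower(gr[1, 1]), "sample_id")) gr <- gr[-1L, , drop = FALSE]
  if (ncol(gr) < 2L)
    tfs_stop("tfscout_format_error", "groups table needs columns sample_id, group")
  groups <- as.character(gr[[2L]])
  names(groups) <- as.character(gr[[1L]])
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    tfs_stop("tfscout_format_error", "sample(s) with no group assignment: %s",
             paste(missing, collapse = ", "))
  new_expr_matrix(values, groups[colnames(values)])
}

#' Construct an expression matrix object in memory
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param groups named character vector mapping every sample (column)
#'   to a group label.
#' @return an `expr_matrix` object.
#' @export
new_expr_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    tfs_stop("tfscout_contract_error", "duplicate gene ids")
  if (!all(colnames(values) %in% names(groups)))
    tfs_stop("tfscout_contract_error", "every sample needs a group")
  structure(list(values = values,
                 groups = as.character(groups[colnames(values)]) |>
                   stats::setNames(colnames(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples in %d group(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups))))
  invisible(x)
}

#' Read a ChIP-seq peak table
#'
#' TSV columns `chrom`, `start`, `end`, `fold_change`, `read_count`;
#' coordinates 0-based half-open. Lines starting with `#` are skipped.
#'
#' @param path path to the peak TSV.
#' @return data.frame of peaks in file order (possibly 0 rows).
#' @export
read_peaks <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), fold_change = numeric(0),
                      read_count = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L))
    tfs_stop("tfscout_format_error", "line %d: expected 5 tab-separated fields",
             line_no[which(lengths(parts) < 5L)[1L]])
  df <- data.frame(
    chrom       = vapply(parts, `[[`, character(1), 1L),
    start       = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end         = as.integer(vapply(parts, `[[`, character(1), 3L)),
    fold_change = as.numeric(vapply(parts, `[[`, character(1), 4L)),
    read_count  = as.integer(vapply(parts, `[[`, character(1), 5L)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad))
    tfs_stop("tfscout_format_error", "line %d: start must be < end",
             line_no[bad[1L]])
  if (any(!is.finite(df$fold_change)))
    tfs_stop("tfscout_format_error", "non-finite fold_change value")
  if (any(is.na(df$read_count) | df$read_count < 0L))
    tfs_stop("tfscout_format_error", "read_count must be a non-negative integer")
  df
}

#' Write a prediction table to TSV
#'
#' Columns: `gene_id`, `r_score`, `best_group`, `k_max1`, `k_max3`,
#' `k_total`, `pass_r`, `pass_pwm`, `pass_all`. Rows are sorted by
#' `pass_all` (passing first), then `r_score` descending, then
#' `gene_id` ascending. Floats are rendered with 6 significant digits.
#'
#' @param records prediction data.frame from [predict_targets()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_prediction_table <- function(records, path) {
  cols <- c("gene_id", "r_score", "best_group", "k_max1", "k_max3",
            "k_total", "pass_r", "pass_pwm", "pass_all")
  stopifnot(all(cols %in% names(records)))
  df <- records[order(-records$pass_all, -records$r_score, records$gene_id),
                cols, drop = FALSE]
  for (cc in c("r_score", "k_max1", "k_max3", "k_total"))
    df[[cc]] <- signif(df[[cc]], 6)
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) tfs_stop("tfscout_io_error", "cannot write to %s", path)
  invisible(path)
}

#' Read a plain gene-id list
#'
#' One gene id per line; blank lines and `#` comments ignored. Used to
#' load a precomputed reference target set in place of peak assignment.
#'
#' @param path path to the list file.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  stopifnot(file.exists(path))
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !grepl("^#", x)])
}
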