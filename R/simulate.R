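# Seeded synthetic benchmark: genomes with planted motif occurrences,
# expression with planted TF-target correlations, and peak files whose
# filtered, promoter-assigned gene set recovers the planted truth.
#
# Genome layout. Each gene owns a disjoint slot of
# promoter_length + 1000 + 250 bp on its chromosome: the promoter, a
# 1000 bp TSS-downstream margin, and a 250 bp intergenic tail used for
# decoy peak placement. Promoter windows (promoter_length upstream,
# <= 1000 bp downstream of the TSS) of different genes therefore never
# overlap, so a peak planted in one gene's promoter is assigned to that
# gene only.

SIM_DOWN_MARGIN <- 1000L
SIM_TAIL <- 250L

#' Configuration for the synthetic benchmark
#'
#' The defaults define the package's standard benchmark: 1000 genes in
#' 10 chromosomes, 50 true targets, correlation effect size 0.8 within
#' each of 5 groups of 100 samples, an 8 bp motif planted once per true
#' target in a 5000 bp promoter of uniform base composition.
#'
#' @param seed integer seed; every generator derives its RNG stream
#'   from it, so fixtures are pure functions of the configuration.
#' @param n_genes number of annotated genes.
#' @param n_groups number of sample groups (cancer types).
#' @param samples_per_group samples in each group.
#' @param n_true_targets number of planted target genes.
#' @param effect_size within-group TF-target correlation rho in [0, 1).
#' @param motif_length motif length n in bp.
#' @param promoter_length promoter length L in bp (>= motif_length).
#' @param motif_plant_rate exact motif copies planted per true target.
#' @param background base probabilities (A, C, G, T) of the genome.
#' @param n_decoy_peaks peaks placed in promoters but failing the
#'   enrichment filter.
#' @param n_intergenic_peaks filter-passing peaks placed outside every
#'   promoter window.
#' @param genes_per_chrom genes per simulated chromosome.
#' @param tf_gene id of the TF's own expression row.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_groups = 5L,
                       samples_per_group = 100L, n_true_targets = 50L,
                       effect_size = 0.8, motif_length = 8L,
                       promoter_length = 5000L, motif_plant_rate = 1L,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_decoy_peaks = 20L, n_intergenic_peaks = 20L,
                       genes_per_chrom = 100L, tf_gene = "TF1") {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_true_targets = as.integer(n_true_targets),
              effect_size = effect_size, motif_length = as.integer(motif_length),
              promoter_length = as.integer(promoter_length),
              motif_plant_rate = as.integer(motif_plant_rate),
              background = background,
              n_decoy_peaks = as.integer(n_decoy_peaks),
              n_intergenic_peaks = as.integer(n_intergenic_peaks),
              genes_per_chrom = as.integer(genes_per_chrom),
              tf_gene = tf_gene)
  with(cfg, {
    if (n_true_targets > n_genes)
      tfs_stop("tfscout_config_error", "n_true_targets exceeds n_genes")
    if (any(c(n_genes, n_groups, samples_per_group, motif_length,
              promoter_length, genes_per_chrom, motif_plant_rate) < 1L))
      tfs_stop("tfscout_config_error", "all counts must be positive")
    if (effect_size < 0 || effect_size >= 1)
      tfs_stop("tfscout_config_error", "effect_size must be in [0, 1)")
    if (promoter_length < motif_length)
      tfs_stop("tfscout_config_error",
               "promoter_length must be >= motif_length")
    if (promoter_length < motif_plant_rate * motif_length)
      tfs_stop("tfscout_config_error", "promoter too short for planted copies")
    if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
      tfs_stop("tfscout_config_error", "background must sum to 1")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a position frequency matrix
#'
#' One dominant base per column (count 85 of 100) so the motif has a
#' well-defined consensus whose self-score — the maximum attainable
#' window score — is known analytically.
#'
#' @param config a `sim_config`.
#' @return a PFM object (`tf_name`, 4 x n `counts`).
#' @export
simulate_pfm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    n <- config$motif_length
    dominant <- sample(1:4, n, replace = TRUE)
    counts <- matrix(5L, nrow = 4L, ncol = n,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(dominant, seq_len(n))] <- 85L
    list(tf_name = config$tf_gene, counts = counts)
  })
}

#' Consensus sequence of a PFM
#'
#' @param pfm a PFM object.
#' @return the consensus string (ties broken by A,C,G,T order).
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2L, which.max)], collapse = "")
}

# slot geometry shared by the generators
sim_layout <- function(config) {
  slot <- config$promoter_length + SIM_DOWN_MARGIN + SIM_TAIL
  n_chrom <- ceiling(config$n_genes / config$genes_per_chrom)
  list(slot = slot, n_chrom = n_chrom)
}

#' Simulate a genome and gene annotation with planted motifs
#'
#' Chromosomes are i.i.d. background sequence carved into disjoint
#' per-gene slots; each gene gets a random strand and a TSS placed so
#' its promoter lies inside its slot. Every planted target receives
#' `motif_plant_rate` exact copies of the PFM consensus at random
#' offsets and orientations within its promoter; other promoters carry
#' only chance matches.
#'
#' @param config a `sim_config`.
#' @param pfm the motif PFM; default [simulate_pfm()] of the same
#'   config.
#' @return list with `genome` (named character vector), `annotations`
#'   (data.frame), `truth` (character vector of planted target ids).
#' @export
simulate_genome_and_annotation <- function(config, pfm = simulate_pfm(config)) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$promoter_length
  n <- config$motif_length
  lay <- sim_layout(config)
  consensus <- pfm_consensus(pfm)
  with_seed(config$seed, {
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
    truth <- sort(sample(gene_ids, config$n_true_targets))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    chrom_of <- sprintf("chr%d", ((seq_len(config$n_genes) - 1L) %/%
                                    config$genes_per_chrom) + 1L)
    idx_in_chrom <- (seq_len(config$n_genes) - 1L) %% config$genes_per_chrom
    slot_start <- idx_in_chrom * lay$slot
    tss <- ifelse(strand == "+", slot_start + L, slot_start + SIM_DOWN_MARGIN - 1L)
    genome <- character(lay$n_chrom)
    names(genome) <- sprintf("chr%d", seq_len(lay$n_chrom))
    bases <- c("A", "C", "G", "T")
    for (ci in seq_len(lay$n_chrom)) {
      in_chrom <- which(chrom_of == names(genome)[ci])
      clen <- length(in_chrom) * lay$slot
      chars <- sample(bases, clen, replace = TRUE,
                      prob = as.numeric(config$background))
      for (gi in in_chrom) {
        if (!gene_ids[gi] %in% truth) next
        # plant copies in disjoint promoter chunks so they never overlap
        chunk <- L %/% config$motif_plant_rate
        for (k in seq_len(config$motif_plant_rate)) {
          offset <- (k - 1L) * chunk + sample.int(chunk - n + 1L, 1L) - 1L
          motif <- if (runif(1) < 0.5) consensus else revcomp(consensus)
          # map promoter offset (0-based, 5'->3' on coding orientation)
          # to genome coordinates
          if (strand[gi] == "+") {
            gstart <- tss[gi] - L + offset          # 0-based
            planted <- strsplit(motif, "")[[1L]]
          } else {
            gstart <- tss[gi] + 1L + (L - offset - n)
            planted <- strsplit(revcomp(motif), "")[[1L]]
          }
          chars[gstart + seq_len(n)] <- planted
        }
      }
      genome[ci] <- paste(chars, collapse = "")
    }
    annotations <- data.frame(gene_id = gene_ids, chrom = chrom_of,
                              tss = as.integer(tss), strand = strand,
                              stringsAsFactors = FALSE)
    list(genome = genome, annotations = annotations, truth = truth)
  })
}

#' Simulate an expression matrix with planted TF-target correlations
#'
#' The TF's expression is standard normal per sample; each planted
#' target is `rho * tf + sqrt(1 - rho^2) * noise` (so its within-group
#' population correlation with the TF is exactly `rho`); every other
#' gene is independent noise.
#'
#' @param config a `sim_config`.
#' @param truth character vector of planted target ids (from
#'   [simulate_genome_and_annotation()]).
#' @param gene_ids all annotated gene ids; default the standard
#'   `g0001..` naming of the same config.
#' @return an `expr_matrix` including the TF's own row.
#' @export
simulate_expression <- function(config, truth,
                                gene_ids = sprintf("g%04d", seq_len(config$n_genes))) {
  stopifnot(inherits(config, "sim_config"), all(truth %in% gene_ids))
  with_seed(config$seed + 1L, {
    n_samples <- config$n_groups * config$samples_per_group
    samples <- sprintf("s%04d", seq_len(n_samples))
    groups <- rep(sprintf("grp%02d", seq_len(config$n_groups)),
                  each = config$samples_per_group)
    names(groups) <- samples
    tf_x <- rnorm(n_samples)
    rho <- config$effect_size
    values <- matrix(rnorm(length(gene_ids) * n_samples),
                     nrow = length(gene_ids),
                     dimnames = list(gene_ids, samples))
    ti <- match(truth, gene_ids)
    values[ti, ] <- rho * matrix(tf_x, nrow = length(ti), ncol = n_samples,
                                 byrow = TRUE) +
      sqrt(1 - rho^2) * values[ti, , drop = FALSE]
    values <- rbind(values, matrix(tf_x, nrow = 1L,
                                   dimnames = list(config$tf_gene, NULL)))
    new_expr_matrix(values, groups)
  })
}

#' Simulate ChIP-seq peaks around planted targets
#'
#' Each planted target gets one filter-passing peak (fold change 2.0,
#' 20 reads) close to its TSS inside its promoter; decoy peaks sit in
#' random promoters but fail the enrichment filter (fold change 1.2 or
#' 5 reads); intergenic peaks pass the filter but fall in the
#' intergenic tails outside every promoter window. Filtering plus
#' promoter assignment therefore recovers exactly the truth set.
#'
#' @param config a `sim_config`.
#' @param truth planted target ids.
#' @param annotations annotation data.frame of the same fixture.
#' @return peak data.frame (`chrom`, `start`, `end`, `fold_change`,
#'   `read_count`).
#' @export
simulate_peaks <- function(config, truth, annotations) {
  stopifnot(inherits(config, "sim_config"), all(truth %in% annotations$gene_id))
  L <- config$promoter_length
  u1 <- min(L, 150L)  # peak anchor: this far TSS-proximal inside the promoter
  width <- min(50L, u1)
  peak_near_tss <- function(rows) {
    start <- ifelse(rows$strand == "+", rows$tss - u1, rows$tss + 1L + u1 - width)
    data.frame(chrom = rows$chrom, start = as.integer(start),
               end = as.integer(start + width), stringsAsFactors = FALSE)
  }
  tail_start_of <- function(rows)
    ifelse(rows$strand == "+", rows$tss + SIM_DOWN_MARGIN, rows$tss + L + 1L)
  with_seed(config$seed + 2L, {
    tr <- annotations[match(truth, annotations$gene_id), , drop = FALSE]
    truth_peaks <- cbind(peak_near_tss(tr), fold_change = 2.0, read_count = 20L)
    decoys <- NULL
    if (config$n_decoy_peaks > 0L) {
      rows <- annotations[sample.int(nrow(annotations), config$n_decoy_peaks,
                                     replace = TRUE), , drop = FALSE]
      low_fc <- runif(config$n_decoy_peaks) < 0.5
      decoys <- cbind(peak_near_tss(rows),
                      fold_change = ifelse(low_fc, 1.2, 2.0),
                      read_count = ifelse(low_fc, 20L, 5L))
    }
    intergenic <- NULL
    if (config$n_intergenic_peaks > 0L) {
      rows <- annotations[sample.int(nrow(annotations), config$n_intergenic_peaks,
                                     replace = TRUE), , drop = FALSE]
      start <- tail_start_of(rows) + 50L
      intergenic <- data.frame(chrom = rows$chrom, start = as.integer(start),
                               end = as.integer(start + 50L),
                               fold_change = 3.0, read_count = 30L,
                               stringsAsFactors = FALSE)
    }
    out <- rbind(truth_peaks, decoys, intergenic)
    rownames(out) <- NULL
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Generates genome, annotation, motif, expression, groups, peaks and
#' the planted truth list, and writes them in the formats the readers
#' of this package consume. All outputs are plain text and
#' deterministic given the configuration.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and the file
#'   paths (`$paths`).
#' @export
simulate_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pfm <- simulate_pfm(config)
  ga <- simulate_genome_and_annotation(config, pfm)
  expr <- simulate_expression(config, ga$truth)
  peaks <- simulate_peaks(config, ga$truth, ga$annotations)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    pfm = file.path(dir, "motif.jaspar"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    peaks = file.path(dir, "peaks.tsv"),
    truth = file.path(dir, "truth_genes.txt")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ga$genome), paths$genome)
  write.table(ga$annotations, paths$annotation, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_jaspar_pfm(pfm, paths$pfm)
  expr_tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr_tab, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(names(expr$groups), unname(expr$groups)),
              paths$groups, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(peaks, paths$peaks, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c("# synthetic planted target genes", ga$truth), paths$truth)
  invisible(list(config = config, pfm = pfm, genome = ga$genome,
                 annotations = ga$annotations, truth = ga$truth,
                 expr = expr, peaks = peaks, paths = paths))
}
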