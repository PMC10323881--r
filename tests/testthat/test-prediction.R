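test_that("percentile cutoffs use the type-7 linear interpolation", {
  expect_equal(resolve_cutoff(c(1, 2, 3, 4), pct(75)), 3.25)
  expect_equal(resolve_cutoff(c(7, 1), 8.0), 8.0)
  expect_equal(resolve_cutoff(5, pct(75)), 5)
  expect_error(resolve_cutoff(numeric(0), pct(75)), class = "tfscout_contract_error")
  expect_error(pct(0), class = "tfscout_contract_error")
  expect_error(pct(100), class = "tfscout_contract_error")
})

mk_summaries <- function(ids, k1) {
  data.frame(gene_id = ids, k_max1 = k1, k_max3 = k1 * 2, k_total = k1 * 3,
             n_windows = 10L, n_skipped_windows = 0L, no_windows = FALSE,
             stringsAsFactors = FALSE)
}
mk_rscores <- function(ids, r) {
  data.frame(gene_id = ids, r_score = r, best_group = "grp01",
             n_groups_evaluated = 5L, stringsAsFactors = FALSE)
}

test_that("strict cutoffs: a gene exactly at a threshold fails that flag", {
  sm <- mk_summaries(c("a", "b", "c"), c(9, 8, 9))
  rs <- mk_rscores(c("a", "b", "c"), c(0.8, 0.8, 0.7))
  out <- predict_targets(sm, rs, cutoff_spec(r_cutoff = 0.7, pwm_cutoff = 8))
  expect_equal(out$pass_all[out$gene_id == "a"], TRUE)
  expect_equal(out$pass_pwm[out$gene_id == "b"], FALSE)   # 8 is not > 8
  expect_equal(out$pass_r[out$gene_id == "c"], FALSE)     # 0.7 is not > 0.7
  expect_identical(out$pass_all, out$pass_r & out$pass_pwm)
})

test_that("the join excludes one-sided genes and reports the counts", {
  sm <- mk_summaries(c("a", "b", "x"), c(9, 9, 9))
  rs <- mk_rscores(c("a", "b", "y", "z"), c(0.9, 0.8, 0.9, 0.9))
  out <- predict_targets(sm, rs)
  expect_setequal(out$gene_id, c("a", "b"))
  expect_equal(attr(out, "n_only_pwm"), 1L)
  expect_equal(attr(out, "n_only_r"), 2L)
  expect_warning(predict_targets(mk_summaries("q", 1), mk_rscores("w", 0.5)),
                 "join is empty")
})

test_that("percentile cutoffs are resolved over the joined table", {
  sm <- mk_summaries(letters[1:4], c(1, 2, 3, 4))
  rs <- mk_rscores(letters[1:4], c(0.1, 0.2, 0.3, 0.4))
  out <- predict_targets(sm, rs, cutoff_spec(r_cutoff = pct(75),
                                             pwm_cutoff = pct(75)))
  expect_equal(attr(out, "resolved_r_cutoff"), 0.325)
  expect_equal(attr(out, "resolved_pwm_cutoff"), 3.25)
  expect_equal(sum(out$pass_all), 1L)  # only the top gene exceeds both
})

test_that("tightening either cutoff never enlarges the pass set", {
  set.seed(43)
  for (i in 1:20) {
    n <- 40
    ids <- paste0("g", 1:n)
    sm <- mk_summaries(ids, rnorm(n, 5, 3))
    rs <- mk_rscores(ids, runif(n, -1, 1))
    r0 <- runif(1, -0.5, 0.5); k0 <- rnorm(1, 5, 2)
    base <- predict_targets(sm, rs, cutoff_spec(r_cutoff = r0, pwm_cutoff = k0))
    tight_r <- predict_targets(sm, rs, cutoff_spec(r_cutoff = r0 + 0.2,
                                                   pwm_cutoff = k0))
    tight_k <- predict_targets(sm, rs, cutoff_spec(r_cutoff = r0,
                                                   pwm_cutoff = k0 + 1))
    base_set <- base$gene_id[base$pass_all]
    expect_true(all(tight_r$gene_id[tight_r$pass_all] %in% base_set))
    expect_true(all(tight_k$gene_id[tight_k$pass_all] %in% base_set))
    # pass_all is exactly the intersection of the single-criterion sets
    expect_setequal(base_set,
                    intersect(base$gene_id[base$pass_r],
                              base$gene_id[base$pass_pwm]))
  }
})

test_that("prediction is deterministic and sorted for output", {
  set.seed(47)
  ids <- paste0("g", 1:20)
  sm <- mk_summaries(ids, rnorm(20, 5, 3))
  rs <- mk_rscores(ids, runif(20))
  a <- predict_targets(sm, rs)
  b <- predict_targets(sm[sample(20), ], rs[sample(20), ])
  expect_equal(a, b, ignore_attr = TRUE)
  expect_true(all(diff(as.integer(!a$pass_all)) >= 0))  # passing rows first
  for (grp in unique(a$pass_all))
    expect_true(all(diff(a$r_score[a$pass_all == grp]) <= 1e-12))
})

test_that("the end-to-end pipeline recovers planted targets at permissive cutoffs", {
  cfg <- sim_config(seed = 5, n_genes = 60, n_true_targets = 8,
                    samples_per_group = 60, n_groups = 3,
                    promoter_length = 250, genes_per_chrom = 20,
                    n_decoy_peaks = 10, n_intergenic_peaks = 10)
  pfm <- simulate_pfm(cfg)
  ga <- simulate_genome_and_annotation(cfg, pfm)
  expr <- simulate_expression(cfg, ga$truth)
  ref <- assign_peaks_to_genes(filter_peaks(simulate_peaks(cfg, ga$truth, ga$annotations)),
                               ga$annotations, window_upstream = 250)
  res <- run_tf_pipeline(ga$genome, ga$annotations, pfm, expr, cfg$tf_gene,
                         cutoffs = cutoff_spec(r_cutoff = 0.45, pwm_cutoff = 0),
                         upstream_length = 250, reference = ref)
  passed <- res$predictions$gene_id[res$predictions$pass_all]
  expect_true(all(ga$truth %in% passed))
  expect_equal(res$evaluation$sensitivity, 1)
  expect_s3_class(res$roc, "roc_curve")
  expect_equal(res$manifest$n_genes_annotated, 60L)
})

test_that("pipeline failures name their stage", {
  cfg <- sim_config(seed = 6, n_genes = 10, n_true_targets = 2,
                    samples_per_group = 10, n_groups = 2,
                    promoter_length = 100, genes_per_chrom = 10)
  pfm <- simulate_pfm(cfg)
  ga <- simulate_genome_and_annotation(cfg, pfm)
  expr <- simulate_expression(cfg, ga$truth)
  err <- tryCatch(
    run_tf_pipeline(ga$genome, ga$annotations, pfm, expr, "NOT_A_GENE",
                    upstream_length = 100),
    error = function(e) e)
  expect_s3_class(err, "tfscout_stage_error")
  expect_match(conditionMessage(err), "expression_correlation")
})

test_that("cutoffs above every observed value give an empty passing set", {
  cfg <- sim_config(seed = 7, n_genes = 10, n_true_targets = 2,
                    samples_per_group = 10, n_groups = 2,
                    promoter_length = 100, genes_per_chrom = 10)
  pfm <- simulate_pfm(cfg)
  ga <- simulate_genome_and_annotation(cfg, pfm)
  expr <- simulate_expression(cfg, ga$truth)
  res <- run_tf_pipeline(ga$genome, ga$annotations, pfm, expr, cfg$tf_gene,
                         cutoffs = cutoff_spec(r_cutoff = 2, pwm_cutoff = 1e6),
                         upstream_length = 100)
  expect_equal(sum(res$predictions$pass_all), 0L)
  expect_equal(nrow(res$predictions), 10L)
})
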