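test_that("pearson_r handles exact cases and signals degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_r(c(1, 2), c(3, 4)), class = "tfscout_insufficient_samples")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "tfscout_zero_variance")
  expect_error(pearson_r(1:4, 1:5), class = "tfscout_contract_error")
})

test_that("pearson_r agrees with the two-pass closed form on random vectors", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_r(x, y), closed_form_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("per-group correlations carry reason codes for undefined groups", {
  e <- make_expr(list(
    g1 = list(TF = c(1, 2, 3), tgt = c(1, 2, 3)),
    g2 = list(TF = c(5, 1), tgt = c(2, 2)),           # too small
    g3 = list(TF = c(2, 2, 2), tgt = c(1, 5, 3))))    # constant TF
  pg <- group_correlations(e, "TF", "tgt")
  expect_equal(pg$r[pg$group == "g1"], 1.0)
  expect_equal(pg$reason[pg$group == "g2"], "insufficient_samples")
  expect_equal(pg$reason[pg$group == "g3"], "zero_variance")
  expect_error(group_correlations(e, "TF", "nope"), class = "tfscout_lookup_error")
})

test_that("the R-score is the maximum over groups, signed by default", {
  e <- make_expr(list(
    g1 = list(TF = c(1, 2, 3, 4), tgt = c(1.4, 1.9, 3.2, 3.9)),
    g2 = list(TF = c(1, 2, 3, 4), tgt = c(4, 3, 2, 1)),
    g3 = list(TF = c(1, 2, 3, 4), tgt = c(2, 1, 4, 3))))
  rs <- r_score(e, "TF", "tgt")
  pg <- rs$per_group_r
  expect_equal(rs$r_score, max(pg$r, na.rm = TRUE))
  expect_equal(pg$r[pg$group == rs$best_group], rs$r_score)
  expect_equal(rs$n_groups_evaluated, 3L)
})

test_that("absolute mode reports |r| while keeping the signed per-group value", {
  e <- make_expr(list(
    g1 = list(TF = c(1, 2, 3, 4), tgt = c(4.1, 2.9, 2.1, 0.9)),  # r ~ -1
    g2 = list(TF = c(1, 2, 3, 4), tgt = c(2, 1, 4, 3))))         # r = 0.6
  rs <- r_score(e, "TF", "tgt", absolute = TRUE)
  expect_equal(rs$best_group, "g1")
  expect_gt(rs$r_score, 0.9)
  expect_lt(rs$per_group_r$r[rs$per_group_r$group == "g1"], 0)

  signed <- r_score(e, "TF", "tgt", absolute = FALSE)
  expect_equal(signed$best_group, "g2")
  expect_equal(signed$r_score, 0.6)
})

test_that("single defined group and total degeneracy are handled", {
  e <- make_expr(list(
    g1 = list(TF = c(1, 2, 3, 4), tgt = c(2, 1, 4, 3)),
    g2 = list(TF = c(9, 9), tgt = c(1, 2))))
  rs <- r_score(e, "TF", "tgt")
  expect_equal(rs$r_score, 0.6)
  expect_equal(rs$n_groups_evaluated, 1L)

  e2 <- make_expr(list(g1 = list(TF = c(1, 1, 1), tgt = c(1, 2, 3))))
  expect_error(r_score(e2, "TF", "tgt"), class = "tfscout_no_score")
})

test_that("r_scores_all excludes the TF, sorts descending, matches r_score", {
  set.seed(21)
  vals <- matrix(rnorm(5 * 30), nrow = 5,
                 dimnames = list(c("TF", paste0("g", 1:4)), paste0("s", 1:30)))
  groups <- setNames(rep(c("a", "b", "c"), each = 10), colnames(vals))
  e <- new_expr_matrix(vals, groups)
  out <- r_scores_all(e, "TF")
  expect_false("TF" %in% out$gene_id)
  expect_equal(nrow(out), 4L)
  expect_true(all(diff(out$r_score) <= 0))
  for (g in out$gene_id) {
    single <- r_score(e, "TF", g)
    expect_equal(out$r_score[out$gene_id == g], single$r_score, tolerance = 1e-12)
    expect_equal(out$best_group[out$gene_id == g], single$best_group)
  }
})

test_that("r_scores_all in absolute mode matches the per-gene path", {
  set.seed(22)
  vals <- matrix(rnorm(4 * 24), nrow = 4,
                 dimnames = list(c("TF", paste0("g", 1:3)), paste0("s", 1:24)))
  vals["g2", ] <- -vals["TF", ] + rnorm(24, sd = 0.1)
  e <- new_expr_matrix(vals, setNames(rep(c("a", "b"), each = 12), colnames(vals)))
  out <- r_scores_all(e, "TF", absolute = TRUE)
  expect_gt(out$r_score[out$gene_id == "g2"], 0.9)
  for (g in out$gene_id)
    expect_equal(out$r_score[out$gene_id == g],
                 r_score(e, "TF", g, absolute = TRUE)$r_score, tolerance = 1e-12)
})

test_that("adding a group never decreases the R-score", {
  set.seed(9)
  for (i in 1:15) {
    base <- list(
      g1 = list(TF = rnorm(6), tgt = rnorm(6)),
      g2 = list(TF = rnorm(6), tgt = rnorm(6)))
    extra <- c(base, list(g3 = list(TF = rnorm(6), tgt = rnorm(6))))
    r2 <- r_score(make_expr(base), "TF", "tgt")$r_score
    r3 <- r_score(make_expr(extra), "TF", "tgt")$r_score
    expect_gte(r3, r2 - 1e-12)
  }
})

test_that("within-group affine transforms with positive slope leave r unchanged", {
  set.seed(13)
  tf <- rnorm(8); tgt <- rnorm(8)
  e1 <- make_expr(list(g1 = list(TF = tf, tgt = tgt)))
  e2 <- make_expr(list(g1 = list(TF = 3.2 * tf + 7, tgt = 0.5 * tgt - 2)))
  expect_equal(r_score(e1, "TF", "tgt")$r_score,
               r_score(e2, "TF", "tgt")$r_score, tolerance = 1e-12)
})

test_that("planted correlations are recovered within the Fisher-z band", {
  # one target with true within-group r = 0.9, two groups of 500 samples
  set.seed(101)
  rho <- 0.9; n <- 500
  tf <- rnorm(2 * n)
  tgt <- rho * tf + sqrt(1 - rho^2) * rnorm(2 * n)
  vals <- rbind(TF = tf, tgt = tgt)
  colnames(vals) <- paste0("s", seq_len(2 * n))
  e <- new_expr_matrix(vals, setNames(rep(c("a", "b"), each = n), colnames(vals)))
  rs <- r_score(e, "TF", "tgt")
  expect_gt(rs$r_score, 0.85)
  expect_lt(rs$r_score, 0.94)
})

test_that("null genes stay below the max-of-groups Fisher-z bound", {
  # an independent gene over 5 groups of 100 samples: max null r <= 0.3
  set.seed(102)
  tf <- rnorm(500); tgt <- rnorm(500)
  vals <- rbind(TF = tf, tgt = tgt)
  colnames(vals) <- paste0("s", 1:500)
  e <- new_expr_matrix(vals, setNames(rep(paste0("g", 1:5), each = 100),
                                      colnames(vals)))
  expect_lte(r_score(e, "TF", "tgt")$r_score, 0.3)
})
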