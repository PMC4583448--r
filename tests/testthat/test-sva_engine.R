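test_that("fold partitions are disjoint, covering, correctly sized, and seed-stable", {
  set.seed(1)
  f <- make_folds(80L, 10L)
  expect_length(f, 8L)
  expect_true(all(lengths(f) == 10L))
  expect_setequal(unlist(f), 1:80)

  set.seed(1)
  f2 <- make_folds(7L, 3L)
  expect_identical(unname(lengths(f2)), c(3L, 3L, 1L))
  expect_setequal(unlist(f2), 1:7)

  set.seed(42); a <- make_folds(30L, 7L)
  set.seed(42); b <- make_folds(30L, 7L)
  expect_identical(a, b)
  expect_error(make_folds(5L, 5L), "smaller")
})

test_that("majority voting follows the tally rule", {
  expect_identical(majority_label(2L, 1L), -1L)
  expect_identical(majority_label(1L, 2L), 1L)
  expect_identical(majority_label(3L, 3L), 0L)
  expect_identical(majority_label(c(0L, 5L, 2L), c(0L, 1L, 9L)),
                   c(0L, -1L, 1L))
  expect_error(majority_label(-1L, 2L), "non-negative")
})

test_that("proclivity normalizes the tally and conserves total vote mass", {
  # three markers, one realization, votes (1 gingivitis, 2 periodontitis)
  pr <- proclivity(matrix(1L, 1, 1), matrix(2L, 1, 1), m = 3L)
  expect_identical(pr$G_votes, 1 / 3)
  expect_identical(pr$P_votes, 2 / 3)

  # all votes gingivitis
  pr <- proclivity(matrix(6L, 4, 2), matrix(0L, 4, 2), m = 4L)
  expect_identical(pr$G_votes, c(1, 1))
  expect_identical(pr$P_votes, c(0, 0))

  # random tallies: G + P = 1 exactly, and one extra periodontitis vote
  # never decreases P_votes
  set.seed(8)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    np <- m * (m - 1) / 2
    Nb <- sample(1:30, 1)
    vg <- matrix(sample(0:np, Nb * 5, TRUE), Nb, 5)
    pr <- proclivity(vg, np - vg, m)
    expect_true(all(pr$G_votes + pr$P_votes == 1))
    r <- sample(Nb, 1); k <- sample(5, 1)
    if (vg[r, k] > 0) {
      vg2 <- vg; vg2[r, k] <- vg2[r, k] - 1L   # flip one vote G -> P
      expect_gte(proclivity(vg2, np - vg2, m)$P_votes[k], pr$P_votes[k])
    }
  }
})

test_that("each sample accrues exactly m(m-1)/2 votes per realization", {
  for (m in c(3L, 4L)) {
    sim <- normalized_cohort(n_gin = 10L, n_per = 10L, m = m, seed = m)
    res <- run_sva(sim$table, sva_config(Nb = 3L, k1 = 4L, seed = 1L))
    np <- m * (m - 1L) / 2L
    expect_equal(ncol(res$pairs), np)
    expect_true(all(res$v_g + res$v_p == np))
    expect_true(all(res$G_votes + res$P_votes == 1))
  }
})

test_that("with m = 2 the ensemble reduces to the lone base classifier", {
  sim <- normalized_cohort(n_gin = 12L, n_per = 12L, m = 2L, seed = 3L)
  for (kind in c("lda", "qda", "nb", "svm")) {
    cfg <- sva_config(Nb = 1L, k1 = 4L, classifier = kind, seed = 17L)
    res <- run_sva(sim$table, cfg)

    # oracle: replay the same fold permutation, train the single classifier
    # on each complement, predict the held-out fold
    set.seed(17L)
    folds <- make_folds(24L, 4L)
    oracle <- integer(24L)
    for (idx in folds) {
      clf <- train_pair_classifier(kind, sim$table$X[, -idx, drop = FALSE],
                                   sim$table$labels[-idx])
      oracle[idx] <- predict(clf, sim$table$X[, idx, drop = FALSE])
    }
    expect_identical(res$per_realization_labels[1L, ], oracle)
  }
})

test_that("a perfectly separating pair dominates every ensemble set", {
  # marker pair (1,2) carries all the signal; markers 3,4 are pure noise
  base <- c(10, 20)
  mom <- group_moments(markers = paste0("M", 1:4),
                       gin_mean = c(base, 50, 60), gin_sd = c(3, 6, 20, 20),
                       per_mean = c(500 * base, 50, 60),
                       per_sd = c(1500, 3000, 20, 20))
  sim <- generate_cohort(cohort_spec(n_gin = 10L, n_per = 10L, moments = mom,
                                     seed = 4L))
  tb <- log_normalize(sim$table)
  res <- run_sva(tb, sva_config(Nb = 5L, k1 = 4L, classifier = "lda",
                                seed = 2L))
  # pair (1,2) is pair index 1 in lexicographic order
  for (r in 1:5) for (k in 1:20) {
    es <- ensemble_sets(res, r, k)
    side <- if (tb$labels[k] == -1L) es$g else es$p
    expect_true(any(side[1, ] == 1L & side[2, ] == 2L))
  }
})

test_that("well-separated cohorts are labelled perfectly and deterministically", {
  sim <- normalized_cohort(n_gin = 15L, n_per = 15L, seed = 5L,
                           moments = separable_moments())
  cfg <- sva_config(Nb = 20L, k1 = 5L, classifier = "lda", seed = 11L)
  res <- run_sva(sim$table, cfg)
  expect_identical(res$aggregate_labels, sim$truth$generating_group)

  res2 <- run_sva(sim$table, cfg)
  expect_identical(res, res2)   # bit-identical under the same seed
})

test_that("proclivities stabilize as realizations accumulate", {
  sim <- normalized_cohort(n_gin = 15L, n_per = 15L, seed = 6L)
  cfg1 <- sva_config(Nb = 60L, k1 = 5L, seed = 1L)
  cfg2 <- sva_config(Nb = 120L, k1 = 5L, seed = 2L)
  r1 <- run_sva(sim$table, cfg1)
  r2 <- run_sva(sim$table, cfg2)
  # realization-level SE of the per-sample vote fraction, from the larger run
  np <- ncol(r1$pairs)
  se <- apply(r2$v_g / np, 2L, sd) / sqrt(cfg1$Nb)
  expect_true(all(abs(r1$G_votes - r2$G_votes) < 3 * pmax(se, 0.005)))
})

test_that("degenerate permutations are redrawn rather than crashing", {
  # 4 + 16: k1 = 5 folds frequently capture too much of the minority class
  sim <- generate_cohort(cohort_spec(n_gin = 4L, n_per = 16L, seed = 7L))
  tb <- log_normalize(sim$table)
  cfg <- sva_config(Nb = 3L, k1 = 5L, seed = 1L)
  suppressWarnings(res <- run_sva(tb, cfg))
  expect_true(all(res$v_g + res$v_p == 6L))
  expect_true(all(res$G_votes + res$P_votes == 1))
})
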