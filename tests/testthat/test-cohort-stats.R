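test_that("Kruskal-Wallis on the three epochs reproduces the rank-sum statistic", {
  kw <- kruskal_wallis_epochs(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-9)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis_epochs(c(1, 1), c(1, 1), c(1, 1)), "identical")
  # null calibration at alpha = 0.05
  set.seed(71)
  rej <- replicate(2000, {
    kruskal_wallis_epochs(rnorm(8), rnorm(10), rnorm(8))$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("elevated-ictal classification needs significance in every epoch", {
  # exact one-tailed p for (4,5,6) vs (1,2,3) is 1/C(6,3) = 0.05 -> flagged
  one <- elevated_ictal_test(list(list(pre = c(1, 2, 3), ictal = c(4, 5, 6))))
  expect_equal(one$p_values[[1]], 0.05, tolerance = 1e-9)
  expect_true(one$elevated_ictal)
  # identical distributions are never flagged
  same <- elevated_ictal_test(list(list(pre = c(1, 2, 3, 4),
                                        ictal = c(1, 2, 3, 4))))
  expect_false(same$elevated_ictal)
  # one elevated epoch is not enough
  mixed <- elevated_ictal_test(list(
    list(pre = c(1, 2, 3), ictal = c(4, 5, 6)),
    list(pre = c(4, 5, 6), ictal = c(1, 2, 3))))
  expect_equal(unname(mixed$epoch_flags), c(TRUE, FALSE))
  expect_false(mixed$elevated_ictal)
  expect_error(elevated_ictal_test(list(list(pre = 1:2, ictal = 1:5))),
               "insufficient")
  # false-flag rate under the null: two ANDed epoch tests
  set.seed(72)
  flags <- replicate(400, {
    elevated_ictal_test(list(
      list(pre = rnorm(20), ictal = rnorm(10)),
      list(pre = rnorm(20), ictal = rnorm(10))))$elevated_ictal
  })
  expect_lte(mean(flags), 0.02) # nominal alpha^2 = 0.0025, allow slack
})

test_that("permutation chi-square matches association strength and the add-one convention", {
  # perfect association in an 8 + 8 cohort
  elev <- rep(c(TRUE, FALSE), each = 8)
  outc <- rep(c(TRUE, FALSE), each = 8)
  res <- permutation_chi_square(elev, outc, n_perm = 2000, seed = 1)
  expect_lte(res$p.value, 0.01)
  expect_equal(unname(res$table[1, 1]), 8)
  # independence: p roughly uniform, mean near 0.5
  set.seed(73)
  ps <- replicate(200, {
    e <- sample(c(TRUE, FALSE), 16, replace = TRUE)
    o <- sample(rep(c(TRUE, FALSE), each = 8))
    if (all(e) || !any(e)) NA_real_
    else permutation_chi_square(e, o, n_perm = 200)$p.value
  })
  # discrete 2x2 statistics make the permutation p conservative
  # (super-uniform), so the null mean sits at or somewhat above 0.5
  expect_gt(mean(ps, na.rm = TRUE), 0.4)
  expect_lt(mean(ps, na.rm = TRUE), 0.8)
  expect_error(permutation_chi_square(rep(TRUE, 8), outc[1:8], 100),
               "degenerate")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(74)
  ps <- replicate(400, {
    e <- sample(rep(c(TRUE, FALSE), each = 8))
    o <- sample(rep(c(TRUE, FALSE), each = 8))
    permutation_chi_square(e, o, n_perm = 199)$p.value
  })
  # super-uniformity: P(p <= t) <= t (allow Monte-Carlo slack)
  for (t in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 400))
})

test_that("AUC equals brute-force pair counting and has the label symmetry", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  set.seed(75)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) labels[c(1, n)] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))
    expect_equal(roc_auc(scores, !labels), 1 - roc_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both")
})

test_that("half-group splitting enumerates label-valid subsets and compares the distributions", {
  # n = 8 group: C(8,4) = 70 subsets before label filtering
  scores <- c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.15, 0.05)
  labels <- rep(c(TRUE, FALSE), each = 4)
  d <- ictonet:::half_split_aucs(scores, labels)
  expect_lte(length(d), 70)
  expect_equal(length(d), 70 - 2 * choose(4, 4) * choose(4, 0)) # 68 valid
  # perfectly separating scores: every half-split AUC is 1
  expect_true(all(d == 1))
  cmp <- half_split_auc_compare(scores, labels, scores, labels)
  expect_equal(cmp$auc_a, 1)
  expect_gte(cmp$p.value, 0.05) # identical groups are not distinguishable
  # identical groups rarely differ across random score sets
  set.seed(76)
  ps <- replicate(60, {
    sc <- rnorm(8)
    half_split_auc_compare(sc, labels, sc, labels)$p.value
  })
  expect_gte(mean(ps >= 0.05), 0.9)
  expect_error(ictonet:::half_split_aucs(1:3, c(TRUE, FALSE, TRUE)),
               "at least 4")
})
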