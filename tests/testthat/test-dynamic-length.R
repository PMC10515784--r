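test_that("per-position Welch tests behave under null, shift and degeneracy", {
  # identical constant groups: p = 1 by convention
  A <- matrix(0.25, 10, 3); B <- matrix(0.25, 12, 3)
  expect_equal(per_position_pvalues(A, B), c(1, 1, 1))
  # differing constants: certainty of change
  expect_equal(per_position_pvalues(A, B + 1), c(0, 0, 0))
  # equal-mean simulation: approximately uniform p distribution
  set.seed(4)
  A <- matrix(rnorm(50 * 400), 50, 400)
  B <- matrix(rnorm(50 * 400), 50, 400)
  p <- per_position_pvalues(A, B)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # a 10-sigma mean shift is detected overwhelmingly
  A <- matrix(rnorm(50), 50, 1); B <- matrix(rnorm(50, mean = 10), 50, 1)
  expect_lt(per_position_pvalues(A, B), 1e-6)
  # mismatched lengths name the aligned-coordinates constraint
  expect_error(per_position_pvalues(matrix(0, 5, 3), matrix(0, 5, 4)),
               "aligned coordinates")
})

test_that("BH q-values equal the brute-force step-up rule", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), method = "bh"),
               rep(0.04, 4))
  expect_equal(qvalues(0.2, method = "bh"), 0.2)
  expect_equal(qvalues(rep(1, 7), method = "bh"), rep(1, 7))
  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_identical(qvalues(p, method = "bh"), brute_force_bh(p))
  }
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(qvalues(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("Storey q-values shrink toward BH * pi0 and fall back when sparse", {
  # fewer than 20 tests: identical to BH
  p_small <- c(0.01, 0.2, 0.04)
  expect_identical(qvalues(p_small, method = "storey"),
                   qvalues(p_small, method = "bh"))
  # mixed null/alternative: pi0 < 1 so storey <= bh, ordering preserved
  set.seed(21)
  p <- c(runif(400), rbeta(100, 0.2, 5))
  qs <- qvalues(p, method = "storey")
  qb <- qvalues(p, method = "bh")
  expect_true(all(qs <= qb + 1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
  # monotone in p: sorting by p sorts q
  expect_true(all(diff(qs[order(p)]) >= -1e-15))
  # permutation invariance
  perm <- sample(length(p))
  expect_equal(qvalues(p[perm], method = "storey")[order(perm)], qs)
})

test_that("dynamic length counts FDR-significant positions", {
  # direct threshold application on a constructed comparison
  set.seed(3)
  A <- matrix(rnorm(20 * 3, mean = 0, sd = 0.02), 20, 3)
  B <- A
  B[, c(1, 3)] <- B[, c(1, 3)] + 1   # large shifts at positions 1 and 3
  res <- compute_dynamic_length(A, B, alpha = 0.05, method = "bh")
  expect_equal(res$significant_positions, c(1L, 3L))
  expect_equal(res$dynamic_length, 2L)
  expect_equal(res$longest_block$length, 1L)
  # identical sample sets: no changes called
  res0 <- compute_dynamic_length(A, A, alpha = 0.05)
  expect_equal(res0$dynamic_length, 0L)
  expect_true(all(res0$p_values == 1))
})

test_that("identical ensembles give dynamic length zero", {
  e <- tiny_ensemble(seed = 5L, n_runs = 4L)
  res <- compute_dynamic_length(profile_samples(e), profile_samples(e))
  expect_equal(res$dynamic_length, 0L)
})

test_that("longest contiguous significant block is reported", {
  q <- c(0.2, 0.01, 0.01, 0.01, 0.3, 0.01)
  blk <- epbdr:::longest_run(which(q <= 0.05), length(q))
  expect_equal(blk$start, 2L); expect_equal(blk$end, 4L)
  expect_equal(blk$length, 3L)
  expect_equal(epbdr:::longest_run(integer(0), 5)$length, 0L)
})
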