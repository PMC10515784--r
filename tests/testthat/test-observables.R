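test_that("average and flipping profiles on hand-made ensembles", {
  zero <- manual_ensemble(list(matrix(0, 4, 3), matrix(0, 4, 3)))
  expect_equal(average_coordinates(zero)$value, c(0, 0, 0))
  half <- manual_ensemble(list(rbind(rep(0, 3), rep(1, 3))))
  expect_equal(average_coordinates(half)$value, c(0.5, 0.5, 0.5))
  # thresholds outside the recorded range pin the flipping profile
  e <- tiny_ensemble()
  expect_equal(flipping_probability(e, -3)$value, rep(1, 12))
  expect_equal(flipping_probability(e, 21)$value, rep(0, 12))
  expect_error(average_coordinates(manual_ensemble(list(matrix(0, 0, 3)))),
               "no recorded snapshots")
})

test_that("bubble occupancy equals the brute-force window check", {
  y <- c(2, 2, 0, 2)
  occ <- bubble_occupancy(y, 1.5, 4)
  expect_true(all(occ[c(1, 2, 4), 1]))
  expect_false(occ[3, 1])
  expect_true(occ[1, 2])
  expect_false(occ[2, 2]); expect_false(occ[3, 2]); expect_false(occ[1, 3])
  expect_true(all(is.na(occ[4, 2:4])))
  expect_identical(occ, brute_force_occupancy(y, 1.5, 4))
  # randomized equivalence and the subset property omega(n,l) => omega(n,l-1)
  set.seed(5)
  for (i in 1:20) {
    y <- runif(12, -1, 3)
    occ <- bubble_occupancy(y, 1.0, 8)
    expect_identical(occ, brute_force_occupancy(y, 1.0, 8))
    for (l in 2:8) {
      idx <- which(occ[, l])
      if (length(idx)) expect_true(all(occ[idx, l - 1]))
    }
  }
  expect_true(all(!bubble_occupancy(rep(-1, 5), 0, 5)[, 1]))
})

test_that("bubble tensor on a single hand snapshot", {
  e <- manual_ensemble(list(matrix(c(2, 2, 0, 2), 1, 4)))
  bt <- bubble_tensor(e, thresholds = 1.5, L_max = 3)
  expect_equal(bt[1, 2, 1], 1)
  expect_equal(bt[2, 2, 1], 0)
  expect_equal(bt[1, 3, 1], 0)
  expect_equal(bt[, 1, 1], c(1, 1, 0, 1))
})

test_that("tensor laws hold exactly on sampled ensembles", {
  e <- tiny_ensemble(seed = 7L)
  thr_grid <- c(0.5, 1, 1.5, 2)
  bt <- bubble_tensor(e, thresholds = thr_grid, L_max = 8)
  vals <- bt[!is.na(bt)]
  expect_true(all(vals >= 0 & vals <= 1))
  # non-increasing in l at fixed (n, thr) and in thr at fixed (n, l)
  d <- dim(bt)
  for (ti in seq_len(d[3])) {
    dl <- t(apply(bt[, , ti], 1L, diff))
    expect_true(all(dl[!is.na(dl)] <= 0))
  }
  for (l in seq_len(d[2])) {
    dthr <- t(apply(bt[, l, ], 1L, diff))
    expect_true(all(dthr[!is.na(dthr)] <= 0))
  }
  # the l = 1 slice is exactly the flipping profile
  for (ti in seq_along(thr_grid)) {
    expect_identical(unname(bt[, 1, ti]),
                     flipping_probability(e, thr_grid[ti])$value)
  }
  expect_error(bubble_tensor(e, thresholds = 1.5, L_max = 50), "L_max")
  expect_error(bubble_tensor(e, thresholds = c(1, 0.5)), "ascending")
})

test_that("maximal-run convention partitions openings by exact extent", {
  # snapshot (2,2,0,2): maximal bubbles are [1,2] and [4,4] only
  e <- manual_ensemble(list(matrix(c(2, 2, 0, 2), 1, 4)))
  bt <- bubble_tensor(e, thresholds = 1.5, L_max = 4, convention = "maximal")
  expect_equal(bt[1, 2, 1], 1)   # run of length 2 starting at 1
  expect_equal(bt[1, 1, 1], 0)   # not maximal at length 1
  expect_equal(bt[4, 1, 1], 1)
  expect_equal(bt[2, 1, 1], 0)
  expect_equal(sum(bt[!is.na(bt)]), 2)
})

test_that("homogeneous periodic-free profile is flat within sampling error", {
  # open chain: compare interior positions only (ends have one neighbour)
  e <- run_ensemble(generate_fixture("homoAT", 20),
                    mcmc_schedule(preheat_steps = 500, measure_steps = 4000,
                                  record_interval = 10, n_runs = 12L,
                                  base_seed = 13L))
  fl <- flipping_probability(e, 1.0)
  interior <- fl[4:17, ]
  pooled_se <- sqrt(mean(interior$stderr^2))
  expect_lt(max(interior$value) - min(interior$value), 4 * pooled_se)
})

test_that("flipping increases with temperature for a homo-AT tract", {
  sa <- generate_fixture("homoAT", 30)
  sch <- function(T0, seed) mcmc_schedule(temperature = T0, preheat_steps = 500,
                                          measure_steps = 2000,
                                          record_interval = 10, n_runs = 20L,
                                          base_seed = seed)
  hot <- flipping_probability(run_ensemble(sa, sch(340, 101L)), 1.5)
  cold <- flipping_probability(run_ensemble(sa, sch(300, 102L)), 1.5)
  mhot <- mean(hot$value); mcold <- mean(cold$value)
  se <- sqrt(sum(hot$stderr^2) / nrow(hot)^2 + sum(cold$stderr^2) / nrow(cold)^2)
  expect_gt(mhot - mcold, 3 * se)
})
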