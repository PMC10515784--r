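test_that("schedule validation and snapshot arithmetic", {
  sch <- tiny_schedule(measure_steps = 100, record_interval = 10)
  expect_equal(epbdr:::n_snapshots(sch), 10L)
  expect_error(mcmc_schedule(measure_steps = 5, record_interval = 10),
               "measure_steps")
  expect_error(mcmc_schedule(temperature = -1), "temperature")
  tr <- run_simulation(dna_sequence("ACGT"),
                       tiny_schedule(measure_steps = 100, record_interval = 10,
                                     n_runs = 1L),
                       run_seed = 1)
  expect_equal(nrow(tr$snapshots), 10L)
  expect_lte(tr$acceptance_count, tr$proposal_count)
})

test_that("proposals are symmetric Gaussian around the current value", {
  set.seed(1)
  # sigma = 0 leaves the coordinate unchanged
  expect_equal(propose_move(0.7, 0), 0.7)
  # CLT bound on the proposal mean
  cur <- 1.3; sigma <- 0.4; n <- 1e5
  cand <- cur + rnorm(n, 0, sigma)
  expect_lt(abs(mean(cand) - cur), 4 * sigma / sqrt(n))
  # per-strand proposals shrink the effective width by sqrt(2)
  set.seed(2); du <- replicate(2000, propose_move(0, 1, strand = "u"))
  set.seed(3); dy <- replicate(2000, propose_move(0, 1, strand = "y"))
  expect_equal(sd(du) * sqrt(2), sd(dy), tolerance = 0.1)
})

test_that("Metropolis rule: always accept downhill, Boltzmann uphill", {
  expect_true(metropolis_accept(-0.1, 310))
  expect_true(metropolis_accept(0, 310))
  kB <- 8.617333262e-5
  expect_equal(metropolis_probability(kB * 310 * log(2), 310), 0.5)
  expect_equal(metropolis_probability(-5, 310), 1)
  # empirical frequency at fixed uphill dE
  set.seed(8)
  n <- 1e5
  acc <- sum(replicate(n, metropolis_accept(0.01, 310)))
  p_exact <- exp(-0.01 / (kB * 310))
  expect_lt(abs(acc / n - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / n))
})

test_that("a sigma-zero sweep accepts everything and moves nothing", {
  s <- dna_sequence("ACGTAC")
  sch <- tiny_schedule(proposal_sigma = 0, measure_steps = 50,
                       record_interval = 5, n_runs = 1L)
  tr <- run_simulation(s, sch, run_seed = 5)
  expect_true(all(tr$snapshots == 0))
  expect_equal(tr$acceptance_count, tr$proposal_count)
})

test_that("running energy equals recompute after many steps", {
  s <- dna_sequence("ATGCATTAGCATCCGA")
  sp <- resolve_site_parameters(s)
  sch <- tiny_schedule(measure_steps = 1000, record_interval = 1000, n_runs = 1L)
  tr <- run_simulation(s, sch, run_seed = 17)
  expect_lt(abs(tr$final_energy - total_energy(tr$final_y, sp)), 1e-8)
})

test_that("compiled and pure-R engines are bit-for-bit interchangeable", {
  s <- dna_sequence("ACGTTAGC")
  for (conv in c("sweep", "single")) {
    for (ps in c(FALSE, TRUE)) {
      sch <- tiny_schedule(measure_steps = 100, record_interval = 10,
                           n_runs = 1L, step_convention = conv,
                           per_strand = ps)
      a <- run_simulation(s, sch, run_seed = 31, engine = "cpp")
      b <- run_simulation(s, sch, run_seed = 31, engine = "r")
      expect_identical(a$snapshots, b$snapshots)
      expect_identical(a$acceptance_count, as.numeric(b$acceptance_count))
      expect_equal(a$final_energy, b$final_energy, tolerance = 1e-12)
    }
  }
})

test_that("simulations are deterministic in the seed", {
  s <- dna_sequence("ACGTAGCTTA")
  sch <- tiny_schedule(n_runs = 4L)
  e1 <- run_ensemble(s, sch)
  e2 <- run_ensemble(s, sch)
  expect_identical(lapply(e1$trajectories, `[[`, "snapshots"),
                   lapply(e2$trajectories, `[[`, "snapshots"))
  # distinct per-run seeds, results independent of M
  seeds4 <- derive_run_seeds(42L, 4L)
  expect_equal(anyDuplicated(seeds4), 0L)
  expect_identical(seeds4[1:2], derive_run_seeds(42L, 2L))
  sch1 <- tiny_schedule(n_runs = 1L)
  expect_identical(run_ensemble(s, sch1)$trajectories[[1L]]$snapshots,
                   e1$trajectories[[1L]]$snapshots)
})

test_that("a near-zero-temperature chain stays frozen at closure", {
  s <- generate_fixture("homoAT", 10)
  sch <- mcmc_schedule(temperature = 1, preheat_steps = 100,
                       measure_steps = 500, record_interval = 10, n_runs = 1L)
  tr <- run_simulation(s, sch, run_seed = 3)
  expect_lt(mean(abs(tr$snapshots)), 0.05)
})

test_that("auto proposal width keeps acceptance in the tuning band", {
  for (s in list(generate_fixture("homoAT", 30), generate_fixture("homoGC", 30))) {
    e <- run_ensemble(s, mcmc_schedule(preheat_steps = 200, measure_steps = 500,
                                       record_interval = 10, n_runs = 4L,
                                       base_seed = 9L))
    expect_gte(acceptance_rate(e), 0.2)
    expect_lte(acceptance_rate(e), 0.7)
  }
})

test_that("ensemble mean energy is consistent with a single long run", {
  sp <- resolve_site_parameters(generate_fixture("homoAT", 10))
  mean_E <- function(tr) {
    apply(tr$snapshots, 1L, function(y) total_energy(y, sp))
  }
  # total energy is a slow collective observable here (every site can wander
  # across the Morse plateau), so both sides need generous burn-in
  short <- mcmc_schedule(preheat_steps = 30000, measure_steps = 20000,
                         record_interval = 20, n_runs = 20L, base_seed = 21L)
  e <- run_ensemble(sp, short)
  per_run <- vapply(e$trajectories, function(tr) mean(mean_E(tr)), numeric(1))
  long <- run_simulation(sp, mcmc_schedule(preheat_steps = 30000,
                                           measure_steps = 400000,
                                           record_interval = 40, n_runs = 1L),
                         run_seed = 77L)
  expect_lt(abs(mean(per_run) - mean(mean_E(long))),
            3 * sd(per_run) / sqrt(length(per_run)))
})
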