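test_that("site parameters map base-pair classes and dinucleotide steps", {
  p <- default_parameters()
  sp <- resolve_site_parameters(dna_sequence("AT"), p)
  expect_equal(sp$D, rep(p$morse_depth[["AT"]], 2))
  expect_equal(sp$a, rep(p$morse_width[["AT"]], 2))
  expect_equal(sp$k_step, p$stacking_k[["AT"]])

  sp2 <- resolve_site_parameters(dna_sequence("ACGT"), p)
  expect_length(sp2$k_step, 3L)
  expect_equal(sp2$k_step,
               unname(p$stacking_k[c("AC", "CG", "GT")]))
  expect_equal(sp2$D, unname(p$morse_depth[c("AT", "GC", "GC", "AT")]))

  expect_error(dna_sequence("ANT"), "position 2")
  expect_error(dna_sequence("A"), "at least 2")
})

test_that("parameter file round-trips and rejects schema violations", {
  p <- default_parameters()
  expect_s3_class(p, "epbd_parameters")
  expect_true(all(p$stacking_k > 0))
  # reverse-complement symmetry of the shipped table
  for (s in names(p$stacking_k)) {
    rc <- epbdr:::revcomp_step(s)
    expect_equal(p$stacking_k[[s]], p$stacking_k[[rc]])
  }
  # a 10-entry canonical table expands to all 16 steps
  canon <- p$stacking_k[c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "GA", "GC", "TA")]
  p10 <- epbd_parameters(p$morse_depth, p$morse_width, canon,
                         p$stacking_rho, p$stacking_b)
  expect_equal(p10$stacking_k, p$stacking_k)

  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("morse_depth: {AT: 0.05, GC: 0.075}",
               "morse_width: {AT: 4.2, GC: 6.9}",
               "stacking: {rho: 2, b: 0.35, k: {AA: 0.025}}",
               "kB: 8.6e-5",
               "bounds: {y_min: -2, y_max: 20}",
               "unexpected_key: 1"), tmp)
  expect_error(read_epbd_parameters(tmp), "unknown parameter-file key")
})

test_that("Morse potential has its closed-form values and shape", {
  expect_identical(morse_potential(0, 0.05, 4.2), 0)
  expect_equal(morse_potential(0.5, 0.05, 4.2), 0.0385041360157, tolerance = 1e-10)
  # plateau: approaches D from below for large positive y
  expect_lt(morse_potential(2, 0.05, 4.2), 0.05)
  expect_equal(morse_potential(50, 0.05, 4.2), 0.05, tolerance = 1e-8)
  # monotone increasing for y > 0, steep wall for y < 0
  y <- seq(0.01, 3, by = 0.01)
  expect_true(all(diff(morse_potential(y, 0.05, 4.2)) > 0))
  expect_gt(morse_potential(-1, 0.05, 4.2), 0.05)
})

test_that("stacking potential is symmetric, anharmonic, and zero on equality", {
  expect_identical(stacking_potential(0.7, 0.7, 0.025, 2, 0.35), 0)
  expect_equal(stacking_potential(1, 0, 0.025, 2, 0.35), 0.030117202243,
               tolerance = 1e-10)
  # rho = 0 reduces to the pure harmonic
  expect_equal(stacking_potential(1.3, 0.2, 0.04, 0, 0.35),
               0.5 * 0.04 * (1.3 - 0.2)^2)
  # symmetry in the two displacements over random pairs
  set.seed(1)
  x <- runif(50, -2, 5); z <- runif(50, -2, 5)
  expect_equal(stacking_potential(x, z, 0.025, 2, 0.35),
               stacking_potential(z, x, 0.025, 2, 0.35))
})

test_that("total energy has open-chain structure and vanishes at closure", {
  p <- default_parameters()
  # all-zero configuration is exactly zero for random sequences
  set.seed(7)
  for (i in 1:5) {
    s <- generate_fixture("promoter_like", sample(5:40, 1), seed = i)
    sp <- resolve_site_parameters(s, p)
    expect_identical(total_energy(rep(0, sp$n), sp), 0)
  }
  # hand-summed 3-mer: one Morse term plus two stacking terms
  sp3 <- epbd_site_params(D = rep(0.05, 3), a = rep(4.2, 3),
                          k_step = rep(0.025, 2), rho = 2, b = 0.35)
  expect_equal(total_energy(c(0, 0.5, 0), sp3), 0.0552473487753,
               tolerance = 1e-10)
  # two non-interacting halves joined by a zero-displacement junction:
  # the junction stacking term vanishes, so the energy adds
  spA <- epbd_site_params(D = rep(0.05, 3), a = rep(4.2, 3), k_step = rep(0.025, 2))
  sp6 <- epbd_site_params(D = rep(0.05, 6), a = rep(4.2, 6), k_step = rep(0.025, 5))
  yA <- c(0.3, 0.8, 0); yB <- c(0, 1.2, 0.1)
  expect_equal(total_energy(c(yA, yB), sp6),
               total_energy(yA, spA) + total_energy(yB, spA),
               tolerance = 1e-12)
  expect_error(total_energy(rep(0, 4), sp3), "length")
})

test_that("delta_energy matches the full-recompute oracle", {
  p <- default_parameters()
  s <- generate_fixture("promoter_like", 25, seed = 3)
  sp <- resolve_site_parameters(s, p)
  set.seed(99)
  for (i in 1:1000) {
    y <- runif(sp$n, -0.5, 3)
    site <- sample(sp$n, 1)
    new_y <- runif(1, -0.5, 3)
    dE <- delta_energy(y, site, new_y, sp)
    y2 <- y; y2[site] <- new_y
    full <- total_energy(y2, sp) - total_energy(y, sp)
    expect_lt(abs(dE - full), 1e-10 * (1 + abs(total_energy(y, sp))))
  }
})

test_that("delta_energy boundary sites touch a single stacking term", {
  sp5 <- epbd_site_params(D = rep(0.05, 5), a = rep(4.2, 5), k_step = rep(0.025, 4))
  y <- c(0.2, 0.1, 0, 0.4, 0.9)
  # site 1: Morse(1) + stacking(1,2) only
  expect_equal(delta_energy(y, 1, 1.1, sp5),
               morse_potential(1.1, 0.05, 4.2) - morse_potential(0.2, 0.05, 4.2) +
                 stacking_potential(0.1, 1.1, 0.025, 2, 0.35) -
                 stacking_potential(0.1, 0.2, 0.025, 2, 0.35),
               tolerance = 1e-14)
  expect_identical(delta_energy(y, 3, y[3], sp5), 0)
  expect_error(delta_energy(y, 2, 25, sp5), class = "epbd_bounds_error")
})

test_that("per-strand coordinates reduce to the stretching coordinate", {
  u <- c(1, 2, 0.5); v <- c(0.2, -0.3, 0.5)
  expect_equal(strand_to_y(u, v), (u - v) / sqrt(2))
  expect_equal(strand_to_y(v, v), c(0, 0, 0))
})
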