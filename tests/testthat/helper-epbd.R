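# Shared fixtures and independent oracles for the test suite.

tiny_schedule <- function(...) {
  args <- list(preheat_steps = 50, measure_steps = 200, record_interval = 10,
               n_runs = 3L, base_seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(mcmc_schedule, args)
}

# Small ensemble on a mixed 12-mer, shared by observable tests.
tiny_ensemble <- function(seed = 42L, n_runs = 3L) {
  run_ensemble(dna_sequence("ATGCATTAGCAT"),
               tiny_schedule(base_seed = seed, n_runs = n_runs))
}

# Build a synthetic ensemble directly from given snapshot matrices (one per
# run), bypassing the sampler -- used to test observables on hand-made data.
manual_ensemble <- function(snapshot_list, bases = NULL) {
  n <- ncol(snapshot_list[[1L]])
  sp <- epbd_site_params(D = rep(0.05, n), a = rep(4.2, n),
                         k_step = rep(0.025, max(0L, n - 1L)),
                         bases = bases %||% rep("A", n))
  sched <- mcmc_schedule(preheat_steps = 0,
                         measure_steps = max(1L, nrow(snapshot_list[[1L]])),
                         record_interval = 1L,
                         n_runs = length(snapshot_list))
  trajectories <- lapply(seq_along(snapshot_list), function(i) {
    structure(list(snapshots = snapshot_list[[i]], run_seed = i,
                   acceptance_count = 0, proposal_count = 0,
                   final_y = snapshot_list[[i]][nrow(snapshot_list[[i]]), ],
                   final_energy = NA_real_),
              class = "epbd_trajectory")
  })
  structure(list(trajectories = trajectories, schedule = sched,
                 site_params = sp, sequence = NULL),
            class = "epbd_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_bases_test <- function(s) strsplit(unclass(s), "", fixed = TRUE)[[1L]]

# Independent brute-force BH step-up: sort p, apply p*(m/i) from the largest
# rank down with a running minimum, cap at 1, unsort.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, (m / i) * ps[i])
    adj[i] <- min(1, run_min)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force window check for bubble occupancy.
brute_force_occupancy <- function(y, thr, L_max) {
  n <- length(y)
  occ <- matrix(NA, n, L_max)
  for (pos in seq_len(n)) for (l in seq_len(L_max)) {
    if (pos + l - 1L <= n) occ[pos, l] <- all(y[pos:(pos + l - 1L)] > thr)
  }
  occ
}
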