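#' Simulate breathing dynamics and write the characteristic outputs
#'
#' End-to-end pipeline for one sequence: runs the Metropolis ensemble, then
#' writes the average-opening profile, the flipping-probability profile (at
#' the first threshold), the long-format bubble tensor, the trajectory dump,
#' and a reproducibility manifest into `out_dir`.
#'
#' @param sequence A [dna_sequence()], plain base string, or path to a
#'   FASTA/text file.
#' @param out_dir Output directory (created if missing).
#' @param params An [epbd_parameters()] object or path to a parameter file.
#' @param schedule An [mcmc_schedule()]; the default mirrors the standard
#'   protocol (310 K, 50,000 + 80,000 steps, 100 runs) and is heavy -- pass
#'   a smaller schedule for quick looks.
#' @param thresholds Bubble/flipping thresholds in Å (ascending).
#' @param L_max Maximum bubble length (default `min(N, 20)`).
#' @param bubble_convention Passed to [bubble_tensor()].
#' @param save_trajectories Write the per-snapshot dump (default TRUE).
#' @param prefix File-name prefix inside `out_dir`.
#' @return Invisibly, a list with the `ensemble`, the computed observables
#'   and the output `files`.
#' @export
epbd_simulate <- function(sequence, out_dir,
                          params = default_parameters(),
                          schedule = mcmc_schedule(),
                          thresholds = c(0.5, 1, 1.5, 2, 2.5),
                          L_max = NULL,
                          bubble_convention = c("inclusive", "maximal"),
                          save_trajectories = TRUE,
                          prefix = "epbd") {
  bubble_convention <- match.arg(bubble_convention)
  seq_file <- NULL
  if (is.character(sequence) && length(sequence) == 1L && file.exists(sequence)) {
    seq_file <- sequence
    sequence <- read_dna(sequence)
  } else if (!inherits(sequence, "dna_sequence")) {
    sequence <- dna_sequence(sequence)
  }
  params_file <- NULL
  if (is.character(params)) {
    params_file <- params
    params <- read_epbd_parameters(params)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ens <- run_ensemble(sequence, schedule, params = params)
  avg <- average_coordinates(ens)
  flip <- flipping_probability(ens, thr = thresholds[1L])
  tens <- bubble_tensor(ens, thresholds = thresholds, L_max = L_max,
                        convention = bubble_convention)

  p <- function(suffix) file.path(out_dir, paste0(prefix, suffix))
  files <- c(average = p("_average_coordinates.tsv"),
             flipping = p("_flipping_probability.tsv"),
             tensor = p("_bubble_tensor.tsv"))
  write_profile(avg, files[["average"]])
  write_profile(flip, files[["flipping"]])
  write_bubble_tensor(tens, files[["tensor"]])
  if (save_trajectories) {
    files <- c(files, trajectories = p("_trajectories.tsv"))
    write_trajectories(ens, files[["trajectories"]])
  }
  inputs <- c(if (!is.null(seq_file)) c(sequence = seq_file),
              if (!is.null(params_file)) c(parameters = params_file))
  manifest <- p("_manifest.yaml")
  write_manifest(manifest, schedule, inputs = inputs, outputs = files,
                 extra = list(sequence_n_bp = length(sequence),
                              thresholds_A = thresholds,
                              bubble_convention = bubble_convention))
  invisible(list(ensemble = ens, average = avg, flipping = flip,
                 tensor = tens, files = files, manifest = manifest))
}

#' Compare the breathing profiles of two alleles
#'
#' Simulates both alleles under a common schedule (or accepts two
#' pre-computed ensembles) and computes the dynamic length: per-position
#' Welch tests on the per-run flipping values, q-factor profile, and the
#' FDR-thresholded set of significantly changed base pairs. Writes the
#' comparison table and a manifest when `out_dir` is given.
#'
#' @param allele_a,allele_b Sequences (objects, strings or file paths) or
#'   `epbd_ensemble` objects.
#' @param out_dir Optional output directory.
#' @param params,schedule As in [epbd_simulate()]; `schedule$base_seed` is
#'   offset for allele B so the two ensembles are independent.
#' @param statistic,thr Profile statistic for the comparison (see
#'   [profile_samples()]).
#' @param alpha FDR level.
#' @param method q-value method (see [qvalues()]).
#' @param prefix File-name prefix.
#' @return The `epbd_dynamic_length` result (invisibly if `out_dir` is
#'   given), with the output file in attribute `file`.
#' @export
epbd_compare <- function(allele_a, allele_b, out_dir = NULL,
                         params = default_parameters(),
                         schedule = mcmc_schedule(),
                         statistic = c("flipping", "average"), thr = 1.5,
                         alpha = 0.05, method = c("storey", "bh"),
                         prefix = "epbd") {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (is.character(params)) params <- read_epbd_parameters(params)
  as_ens <- function(x, seed_offset) {
    if (inherits(x, "epbd_ensemble")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_dna(x)
    if (!inherits(x, "dna_sequence")) x <- dna_sequence(x)
    sch <- schedule
    sch$base_seed <- schedule$base_seed + seed_offset
    run_ensemble(x, sch, params = params)
  }
  ensA <- as_ens(allele_a, 0L)
  ensB <- as_ens(allele_b, 500000L)
  sA <- profile_samples(ensA, statistic = statistic, thr = thr)
  sB <- profile_samples(ensB, statistic = statistic, thr = thr)
  res <- compute_dynamic_length(sA, sB, alpha = alpha, method = method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, paste0(prefix, "_dynamic_length.tsv"))
    write_dynamic_length(res, f)
    write_manifest(file.path(out_dir, paste0(prefix, "_compare_manifest.yaml")),
                   schedule, outputs = f,
                   extra = list(alpha = alpha, method = method,
                                statistic = statistic, threshold_A = thr))
    attr(res, "file") <- f
    return(invisible(res))
  }
  res
}

#' Reference quadrature report
#'
#' Computes the 1-bp quadrature averages (mean opening and flipping
#' probability above `thr`) for the A·T and G·C base-pair classes, and the
#' 2-bp joint-opening probability for an A·T dimer, at the given
#' temperature. Intended for validating custom parameter files against the
#' sampler.
#'
#' @param params An [epbd_parameters()] object or parameter-file path.
#' @param temperature Temperature (K).
#' @param thr Flipping threshold (Å).
#' @return A data frame with columns `system`, `quantity`, `value`.
#' @export
epbd_oracle_report <- function(params = default_parameters(),
                               temperature = 310, thr = 1.5) {
  if (is.character(params)) params <- read_epbd_parameters(params)
  bounds <- c(params$y_min_bound, params$y_max_bound)
  row <- function(system, quantity, value)
    data.frame(system = system, quantity = quantity, value = value)
  out <- list()
  for (cls in c("AT", "GC")) {
    D <- params$morse_depth[[cls]]
    a <- params$morse_width[[cls]]
    out[[length(out) + 1L]] <- row(paste0("1bp_", cls), "mean_opening_A",
      boltzmann_average_1bp(D, a, temperature, identity, bounds, params$kB))
    out[[length(out) + 1L]] <- row(paste0("1bp_", cls),
      sprintf("flipping_prob_thr%g", thr),
      boltzmann_average_1bp(D, a, temperature, function(y) y > thr, bounds, params$kB))
  }
  sp2 <- resolve_site_parameters(dna_sequence("AA"), params)
  out[[length(out) + 1L]] <- row("2bp_AA", sprintf("joint_open_prob_thr%g", thr),
    boltzmann_average_2bp(sp2, temperature,
                          function(y1, y2) (y1 > thr) & (y2 > thr)))
  do.call(rbind, out)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/epbd` Rscript: subcommands
#' `simulate`, `compare` and `oracle`, mapping flags onto [epbd_simulate()],
#' [epbd_compare()] and [epbd_oracle_report()]. Exposed as a function so the
#' interface is testable without spawning a process.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `c("simulate", "--seq-text", "f.txt", "--out-dir", "o")`.
#' @return Exit status (0 on success), invisibly. Usage errors signal a
#'   condition of class `epbd_usage_error`.
#' @export
epbd_cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: epbd <simulate|compare|oracle> [options]",
    "  simulate --fasta F | --seq-text F  --out-dir D [--params P] [--temp K]",
    "           [--preheat N] [--steps N] [--record-interval N] [--runs M]",
    "           [--seed S] [--thresholds a,b,...] [--max-bubble-length L]",
    "           [--step-convention sweep|single] [--bubble-convention inclusive|maximal]",
    "  compare  --fasta-a F --fasta-b F --out-dir D [--alpha A] [same schedule flags]",
    "  oracle   [--params P] [--temp K] [--threshold T]", sep = "\n")
  fail <- function(msg) {
    stop(structure(class = c("epbd_usage_error", "error", "condition"),
                   list(message = paste0(msg, "\n", usage), call = NULL)))
  }
  if (length(args) < 1L) fail("missing subcommand")
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- parse_flags(rest, fail)
  g <- function(name, default = NULL) opt[[name]] %||% default
  sch <- function() mcmc_schedule(
    temperature = as.numeric(g("temp", 310)),
    preheat_steps = as.numeric(g("preheat", 50000)),
    measure_steps = as.numeric(g("steps", 80000)),
    record_interval = as.integer(g("record-interval", 100)),
    step_convention = g("step-convention", "sweep"),
    base_seed = as.integer(g("seed", 1)),
    n_runs = as.integer(g("runs", 100)))
  params <- g("params", default_parameters())
  switch(cmd,
    simulate = {
      seqf <- g("fasta") %||% g("seq-text") %||% fail("simulate needs --fasta or --seq-text")
      if (!is.null(g("fasta")) && !is.null(g("seq-text")))
        fail("--fasta and --seq-text conflict")
      outd <- g("out-dir") %||% fail("simulate needs --out-dir")
      thr <- as.numeric(strsplit(g("thresholds", "0.5,1,1.5,2,2.5"), ",")[[1L]])
      lm <- g("max-bubble-length"); if (!is.null(lm)) lm <- as.integer(lm)
      res <- epbd_simulate(seqf, outd, params = params, schedule = sch(),
                           thresholds = thr, L_max = lm,
                           bubble_convention = g("bubble-convention", "inclusive"))
      message("wrote ", length(res$files), " output files + manifest to ", outd)
    },
    compare = {
      fa <- g("fasta-a") %||% fail("compare needs --fasta-a")
      fb <- g("fasta-b") %||% fail("compare needs --fasta-b")
      outd <- g("out-dir") %||% fail("compare needs --out-dir")
      res <- epbd_compare(fa, fb, out_dir = outd, params = params,
                          schedule = sch(),
                          alpha = as.numeric(g("alpha", 0.05)),
                          method = g("method", "storey"))
      message("dynamic length: ", res$dynamic_length)
    },
    oracle = {
      rep <- epbd_oracle_report(params = params,
                                temperature = as.numeric(g("temp", 310)),
                                thr = as.numeric(g("threshold", 1.5)))
      write.table(format(rep, digits = 10), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    fail(paste0("unknown subcommand '", cmd, "'")))
  invisible(0L)
}

parse_flags <- function(args, fail) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) fail(paste0("unexpected argument '", a, "'"))
    key <- substring(a, 3L)
    if (i + 1L > length(args) || startsWith(args[i + 1L], "--"))
      fail(paste0("flag --", key, " needs a value"))
    if (!is.null(opt[[key]])) fail(paste0("flag --", key, " given twice"))
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}
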