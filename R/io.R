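fmt_num <- function(x) {
  # 17 significant digits: lossless double round-trip in text
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

schedule_header <- function(schedule) {
  c(sprintf("# temperature_K\t%g", schedule$temperature),
    sprintf("# preheat_steps\t%g", schedule$preheat_steps),
    sprintf("# measure_steps\t%g", schedule$measure_steps),
    sprintf("# record_interval\t%d", schedule$record_interval),
    sprintf("# step_convention\t%s", schedule$step_convention),
    sprintf("# n_runs\t%d", schedule$n_runs),
    sprintf("# base_seed\t%d", schedule$base_seed))
}

#' Write a profile to a tab-separated file
#'
#' Columns `position` (1-based), `base`, `value`, `stderr`; `#`-prefixed
#' header lines carry the profile type, threshold and schedule metadata.
#' Values are written with 17 significant digits, so the file round-trips
#' losslessly through [read_profile()].
#'
#' @param profile An `epbd_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  thr <- attr(profile, "threshold")
  hdr <- c(sprintf("# profile_type\t%s", attr(profile, "type")),
           if (!is.na(thr)) sprintf("# threshold_A\t%g", thr),
           schedule_header(attr(profile, "schedule")),
           "position\tbase\tvalue\tstderr")
  rows <- sprintf("%d\t%s\t%s\t%s", profile$position, profile$base,
                  fmt_num(profile$value), fmt_num(profile$stderr))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A data frame with columns `position`, `base`, `value`, `stderr`;
#'   header metadata in attribute `metadata`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", colClasses = c("integer", "character",
                                              "numeric", "numeric"))
  attr(df, "metadata") <- meta
  df
}

#' Write a bubble tensor in long format
#'
#' Tab-separated columns `n`, `l`, `thr`, `P` (valid windows only), with
#' lossless 17-significant-digit values.
#'
#' @param tensor An `epbd_bubble_tensor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bubble_tensor <- function(tensor, path) {
  long <- tensor_to_long(tensor)
  hdr <- c(sprintf("# convention\t%s", attr(tensor, "convention")),
           "n\tl\tthr\tP")
  rows <- sprintf("%d\t%d\t%s\t%s", long$n, long$l, fmt_num(long$thr),
                  fmt_num(long$P))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a long-format bubble tensor file
#'
#' @param path Path written by [write_bubble_tensor()].
#' @return A data frame with columns `n`, `l`, `thr`, `P`.
#' @export
read_bubble_tensor <- function(path) {
  lines <- readLines(path)
  read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t",
             colClasses = c("integer", "integer", "numeric", "numeric"))
}

#' Write a trajectory dump
#'
#' One row per recorded snapshot across all runs: columns `run`, `step`,
#' `y_1..y_N`. A `.gz` suffix writes a gzip-compressed file.
#'
#' @param ensemble An `epbd_ensemble`.
#' @param path Output path (optionally ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path) {
  n <- ensemble$site_params$n
  ri <- ensemble$schedule$record_interval
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("run", "step", paste0("y_", seq_len(n))), collapse = "\t"), con)
  for (m in seq_along(ensemble$trajectories)) {
    sn <- ensemble$trajectories[[m]]$snapshots
    steps <- ri * seq_len(nrow(sn))
    body <- apply(sn, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
    writeLines(sprintf("%d\t%d\t%s", m, steps, body), con)
  }
  invisible(path)
}

#' Write the dynamic-length comparison table
#'
#' Tab-separated columns `position`, `base_A`, `base_B`, `p`, `q`,
#' `significant`, preceded by a one-line `#` summary (dynamic length, alpha,
#' method).
#'
#' @param result An `epbd_dynamic_length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dynamic_length <- function(result, path) {
  n <- length(result$p_values)
  bA <- result$bases_A %||% rep("N", n)
  bB <- result$bases_B %||% rep("N", n)
  sig <- seq_len(n) %in% result$significant_positions
  hdr <- c(sprintf("# dynamic_length\t%d\talpha\t%g\tmethod\t%s",
                   result$dynamic_length, result$alpha, result$method),
           "position\tbase_A\tbase_B\tp\tq\tsignificant")
  rows <- sprintf("%d\t%s\t%s\t%s\t%s\t%d", seq_len(n), bA, bB,
                  fmt_num(result$p_values), fmt_num(result$q_values), sig)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a run manifest
#'
#' A structured-text (YAML) record sufficient to reproduce every output
#' bit-for-bit: package version, input checksums, full schedule, per-run
#' seeds and the output file list.
#'
#' @param path Manifest path.
#' @param schedule The [mcmc_schedule()] used.
#' @param inputs Named character vector of input file paths (checksummed
#'   with MD5).
#' @param outputs Character vector of output file paths.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, schedule, inputs = character(), outputs = character(),
                           extra = list()) {
  checksums <- if (length(inputs) > 0L) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), names(inputs)))
  } else list()
  manifest <- c(list(
    tool = "epbdr",
    version = as.character(packageVersion("epbdr")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    schedule = list(temperature_K = schedule$temperature,
                    preheat_steps = schedule$preheat_steps,
                    measure_steps = schedule$measure_steps,
                    record_interval = schedule$record_interval,
                    proposal_sigma = schedule$proposal_sigma,
                    step_convention = schedule$step_convention,
                    per_strand = schedule$per_strand,
                    init = schedule$init,
                    base_seed = schedule$base_seed,
                    n_runs = schedule$n_runs),
    run_seeds = derive_run_seeds(schedule$base_seed, schedule$n_runs),
    input_md5 = checksums,
    outputs = as.list(basename(outputs))),
    extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
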