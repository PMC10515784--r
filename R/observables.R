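# Matrix of per-run profile values: one row per run. `fun` maps a snapshot
# matrix (snapshots x N) to a length-N summary.
per_run_profiles <- function(ensemble, fun) {
  n <- ensemble$site_params$n
  vals <- vapply(ensemble$trajectories, function(tr) fun(tr$snapshots), numeric(n))
  if (n == 1L) matrix(vals, ncol = 1L) else t(vals)
}

new_profile <- function(ensemble, run_values, type, threshold = NA_real_) {
  m <- nrow(run_values)
  value <- colMeans(run_values)
  stderr <- if (m >= 2L) apply(run_values, 2L, sd) / sqrt(m) else rep(NA_real_, ncol(run_values))
  structure(data.frame(position = seq_len(ncol(run_values)),
                       base = ensemble$site_params$bases,
                       value = value, stderr = stderr),
            class = c("epbd_profile", "data.frame"),
            type = type, threshold = threshold,
            n_runs = m, schedule = ensemble$schedule)
}

#' @export
print.epbd_profile <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf("<epbd_profile> %s%s, %d positions, M=%d runs\n",
              attr(x, "type"),
              if (!is.na(thr)) sprintf(" (thr=%g A)", thr) else "",
              nrow(x), attr(x, "n_runs")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more positions\n")
  invisible(x)
}

check_nonempty <- function(ensemble) {
  if (length(ensemble$trajectories) == 0L ||
      nrow(ensemble$trajectories[[1L]]$snapshots) == 0L)
    stop("ensemble holds no recorded snapshots", call. = FALSE)
}

#' Average opening profile
#'
#' The per-position mean transverse displacement `<y_n>` over all recorded
#' snapshots of all runs, with the standard error of the per-run means
#' across runs (honest run-to-run uncertainty; per-run means are averaged
#' first, then across runs).
#'
#' @param ensemble An `epbd_ensemble` from [run_ensemble()].
#' @return An `epbd_profile` data frame with columns `position`, `base`,
#'   `value` (Å), `stderr`.
#' @export
average_coordinates <- function(ensemble) {
  check_nonempty(ensemble)
  rv <- per_run_profiles(ensemble, colMeans)
  new_profile(ensemble, rv, type = "average_coordinates")
}

#' Base-flipping probability profile
#'
#' The per-position probability that the displacement exceeds a threshold,
#' estimated as the fraction of recorded snapshots with `y_n > thr`
#' (strictly), per run, then averaged across runs.
#'
#' @param ensemble An `epbd_ensemble`.
#' @param thr Threshold displacement in Å (default 1.5).
#' @return An `epbd_profile` with values in \[0, 1\].
#' @export
flipping_probability <- function(ensemble, thr = 1.5) {
  check_nonempty(ensemble)
  rv <- per_run_profiles(ensemble, function(s) colMeans(s > thr))
  new_profile(ensemble, rv, type = "flipping_probability", threshold = thr)
}

#' Bubble occupancy map of one configuration
#'
#' For a single displacement snapshot, the boolean window map
#' `omega(n, l) = all(y[n..n+l-1] > thr)` (inclusive convention): a bubble
#' of length `l` starting at base pair `n` is open when every position of
#' the window exceeds the threshold. Windows running past the chain end are
#' `NA`.
#'
#' @param y Displacement vector (Å).
#' @param thr Threshold (Å).
#' @param L_max Maximum window length (<= length(y)).
#' @return Logical N x L_max matrix; entry (n, l) is the window starting at
#'   n with length l.
#' @export
bubble_occupancy <- function(y, thr, L_max = min(length(y), 20L)) {
  n <- length(y)
  if (L_max > n) stop("L_max exceeds the sequence length", call. = FALSE)
  occ <- matrix(NA, n, L_max)
  open <- y > thr
  occ[, 1L] <- open
  if (L_max >= 2L) for (l in 2:L_max) {
    idx <- seq_len(n - l + 1L)
    occ[idx, l] <- occ[idx, l - 1L] & open[idx + l - 1L]
  }
  occ
}

# Per-run occupancy fractions for one threshold, inclusive convention.
# snaps: snapshots x N logical matrix of openness is derived inside.
run_bubble_fractions <- function(snaps, thr, L_max, convention) {
  n <- ncol(snaps)
  S <- nrow(snaps)
  open <- snaps > thr
  P <- matrix(NA_real_, n, L_max)
  if (convention == "inclusive") {
    ok <- open
    P[, 1L] <- colMeans(ok)
    if (L_max >= 2L) for (l in 2:L_max) {
      w <- n - l + 1L
      ok <- ok[, seq_len(w), drop = FALSE] & open[, l:n, drop = FALSE]
      P[seq_len(w), l] <- colMeans(ok)
    }
  } else {  # maximal run: closed (or chain end) on both flanks
    closed <- !open
    leftC <- cbind(rep(TRUE, S), closed)    # position n-1 closed, or n == 1
    rightC <- cbind(closed, rep(TRUE, S))   # position n+l closed, or window ends at N
    ok <- open
    for (l in seq_len(L_max)) {
      w <- n - l + 1L
      if (l >= 2L) ok <- ok[, seq_len(w), drop = FALSE] & open[, l:n, drop = FALSE]
      exact <- ok[, seq_len(w), drop = FALSE] &
        leftC[, seq_len(w), drop = FALSE] &
        rightC[, l + seq_len(w), drop = FALSE]
      P[seq_len(w), l] <- colMeans(exact)
    }
  }
  P
}

#' Bubble-probability tensor
#'
#' The equilibrium probability `P(n, l, thr)` that a bubble of length `l`
#' base pairs with amplitude above `thr` exists starting at base pair `n`:
#' the time fraction of recorded snapshots in which all `l` positions of the
#' window are simultaneously open, averaged over runs (per-run fraction
#' first, then the mean across the M runs). Time is measured in recorded
#' snapshots, since openings are only observed at recording times.
#'
#' Under the default inclusive-window convention the tensor is non-increasing
#' in `l` and in `thr`, and its `l = 1` slice is exactly the flipping
#' profile. `convention = "maximal"` instead counts maximal open runs
#' (closed or chain end on both flanks), which decomposes openings by exact
#' bubble extent but loses those monotonicities.
#'
#' @param ensemble An `epbd_ensemble`.
#' @param thresholds Ascending vector of amplitude thresholds (Å).
#' @param L_max Maximum bubble length (<= N).
#' @param convention `"inclusive"` (default) or `"maximal"`.
#' @return An `epbd_bubble_tensor`: 3-D array \[position, length,
#'   threshold\] with `NA` where the window runs past the chain end;
#'   attributes `thresholds`, `convention`.
#' @export
bubble_tensor <- function(ensemble, thresholds = c(0.5, 1, 1.5, 2, 2.5),
                          L_max = NULL, convention = c("inclusive", "maximal")) {
  convention <- match.arg(convention)
  check_nonempty(ensemble)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  n <- ensemble$site_params$n
  if (is.null(L_max)) L_max <- min(n, 20L)
  if (L_max > n) stop("L_max exceeds the sequence length", call. = FALSE)
  M <- length(ensemble$trajectories)
  P <- array(0, dim = c(n, L_max, length(thresholds)))
  for (ti in seq_along(thresholds)) {
    # per-run fractions first, then the across-run mean (matching the
    # flipping profile's accumulation exactly, so the l = 1 slice is
    # bit-identical to flipping_probability)
    arr <- vapply(ensemble$trajectories, function(tr) {
      run_bubble_fractions(tr$snapshots, thresholds[ti], L_max, convention)
    }, matrix(0, n, L_max))
    P[, , ti] <- rowMeans(arr, dims = 2L)
  }
  structure(P, class = "epbd_bubble_tensor",
            thresholds = thresholds, convention = convention)
}

#' @export
print.epbd_bubble_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<epbd_bubble_tensor> %d positions x %d lengths x %d thresholds (%s convention)\n",
              d[1L], d[2L], d[3L], attr(x, "convention")))
  cat("  thresholds (A):", paste(attr(x, "thresholds"), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a bubble tensor
#'
#' @param tensor An `epbd_bubble_tensor`.
#' @return A data frame with columns `n`, `l`, `thr`, `P` (valid windows
#'   only).
#' @export
tensor_to_long <- function(tensor) {
  thr <- attr(tensor, "thresholds")
  d <- dim(tensor)
  out <- expand.grid(n = seq_len(d[1L]), l = seq_len(d[2L]), thr = thr,
                     KEEP.OUT.ATTRS = FALSE)
  out$P <- as.vector(unclass(tensor))
  out[!is.na(out$P), , drop = FALSE]
}
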