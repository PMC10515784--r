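DINUCLEOTIDES <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                   "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")

revcomp_step <- function(step) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(step, "", fixed = TRUE)[[1L]]
  paste0(comp[b[2L]], comp[b[1L]])
}

#' EPBD model parameters
#'
#' Container for the potential-energy parameters of the EPBD model: per
#' base-pair-class Morse well depths `D` (eV) and inverse widths `a` (1/Å),
#' a per-dinucleotide harmonic stacking table `k` (eV/Å²), the anharmonicity
#' amplitude `rho` and range `b` (1/Å) shared by all steps, the Boltzmann
#' constant (eV/K), and the hard displacement bounds (Å) of the sampled
#' domain.
#'
#' The stacking table is keyed by the ordered dinucleotide step
#' (base n-1, base n) on the reference strand. Steps missing from `stacking_k`
#' are filled from their reverse-complement partner, so a 10-entry canonical
#' table is accepted; with `canonical = TRUE` the table is additionally
#' symmetrised (averaged over reverse-complement pairs), enforcing the
#' 10-unique-value convention.
#'
#' @param morse_depth Named numeric, entries `AT` and `GC`, in eV; both > 0.
#' @param morse_width Named numeric, entries `AT` and `GC`, in 1/Å; both > 0.
#' @param stacking_k Named numeric over dinucleotide steps, eV/Å²; all > 0.
#' @param stacking_rho Dimensionless anharmonicity amplitude, >= 0.
#' @param stacking_b Anharmonicity range, 1/Å, >= 0.
#' @param kB Boltzmann constant, eV/K.
#' @param y_min_bound,y_max_bound Hard displacement bounds in Å, with
#'   `y_min_bound < 0 < y_max_bound`. The Morse plateau makes the unbounded
#'   partition function divergent, so equilibrium sampling is defined on this
#'   bounded domain; proposals outside it are rejected, and the quadrature
#'   oracles integrate over exactly the same bounds.
#' @param canonical Enforce reverse-complement symmetry of `stacking_k`.
#' @return An object of class `epbd_parameters`.
#' @seealso [read_epbd_parameters()] for loading a parameter file,
#'   [default_parameters()] for the shipped defaults.
#' @export
epbd_parameters <- function(morse_depth, morse_width, stacking_k,
                            stacking_rho, stacking_b,
                            kB = 8.617333262e-5,
                            y_min_bound = -2, y_max_bound = 20,
                            canonical = FALSE) {
  need <- function(x, keys, what) {
    if (!all(keys %in% names(x)))
      stop(sprintf("%s must have entries %s", what, paste(setdiff(keys, names(x)), collapse = ", ")),
           call. = FALSE)
    x <- unlist(x)[keys]
    storage.mode(x) <- "double"
    x
  }
  morse_depth <- need(morse_depth, c("AT", "GC"), "morse_depth")
  morse_width <- need(morse_width, c("AT", "GC"), "morse_width")
  stacking_k <- unlist(stacking_k)
  storage.mode(stacking_k) <- "double"
  unknown <- setdiff(names(stacking_k), DINUCLEOTIDES)
  if (length(unknown) > 0L)
    stop("unknown stacking step(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  # fill missing steps from reverse-complement partners
  full <- stats::setNames(rep(NA_real_, 16L), DINUCLEOTIDES)
  full[names(stacking_k)] <- stacking_k
  for (s in DINUCLEOTIDES) {
    if (is.na(full[s])) full[s] <- full[revcomp_step(s)]
  }
  if (anyNA(full))
    stop("stacking table incomplete: no value for step(s) ",
         paste(names(full)[is.na(full)], collapse = ", "), call. = FALSE)
  if (canonical) {
    for (s in DINUCLEOTIDES) {
      rc <- revcomp_step(s)
      m <- (full[s] + full[rc]) / 2
      full[s] <- m; full[rc] <- m
    }
  }
  stopifnot(all(morse_depth > 0), all(morse_width > 0), all(full > 0),
            stacking_rho >= 0, stacking_b >= 0, kB > 0,
            y_min_bound < 0, y_max_bound > 0)
  structure(list(morse_depth = morse_depth, morse_width = morse_width,
                 stacking_k = full, stacking_rho = as.numeric(stacking_rho),
                 stacking_b = as.numeric(stacking_b), kB = as.numeric(kB),
                 y_min_bound = as.numeric(y_min_bound),
                 y_max_bound = as.numeric(y_max_bound)),
            class = "epbd_parameters")
}

#' @export
print.epbd_parameters <- function(x, ...) {
  cat("<epbd_parameters>\n")
  cat(sprintf("  Morse D (eV): AT=%.4g GC=%.4g; a (1/A): AT=%.4g GC=%.4g\n",
              x$morse_depth["AT"], x$morse_depth["GC"],
              x$morse_width["AT"], x$morse_width["GC"]))
  cat(sprintf("  stacking k (eV/A^2) in [%.4g, %.4g]; rho=%.3g b=%.3g\n",
              min(x$stacking_k), max(x$stacking_k), x$stacking_rho, x$stacking_b))
  cat(sprintf("  bounds [%g, %g] A; kB=%.6g eV/K\n",
              x$y_min_bound, x$y_max_bound, x$kB))
  invisible(x)
}

#' Read an EPBD parameter file
#'
#' Parses the YAML parameter format shipped at
#' `system.file("extdata", "epbd_params_default.yaml", package = "epbdr")`.
#' The schema is strict: unknown top-level or nested keys are errors, and all
#' required sections must be present.
#'
#' @param path Path to a YAML parameter file.
#' @param canonical Passed to [epbd_parameters()].
#' @return An [epbd_parameters()] object.
#' @export
read_epbd_parameters <- function(path, canonical = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c("morse_depth", "morse_width", "stacking", "kB", "bounds")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L)
    stop("unknown parameter-file key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(allowed, names(raw))
  if (length(missing) > 0L)
    stop("parameter file missing section(s): ", paste(missing, collapse = ", "), call. = FALSE)
  sub_unknown <- setdiff(names(raw$stacking), c("rho", "b", "k"))
  if (length(sub_unknown) > 0L)
    stop("unknown stacking key(s): ", paste(sub_unknown, collapse = ", "), call. = FALSE)
  bad_bounds <- setdiff(names(raw$bounds), c("y_min", "y_max"))
  if (length(bad_bounds) > 0L)
    stop("unknown bounds key(s): ", paste(bad_bounds, collapse = ", "), call. = FALSE)
  epbd_parameters(morse_depth = raw$morse_depth,
                  morse_width = raw$morse_width,
                  stacking_k = raw$stacking$k,
                  stacking_rho = raw$stacking$rho,
                  stacking_b = raw$stacking$b,
                  kB = raw$kB,
                  y_min_bound = raw$bounds$y_min,
                  y_max_bound = raw$bounds$y_max,
                  canonical = canonical)
}

#' Default EPBD parameters
#'
#' Loads the parameter file shipped with the package (classic homogeneous
#' Morse constants for A·T and G·C pairs; an illustrative
#' reverse-complement-symmetric dinucleotide stacking table around
#' 0.025 eV/Å²).
#'
#' @inheritParams read_epbd_parameters
#' @return An [epbd_parameters()] object.
#' @export
default_parameters <- function(canonical = FALSE) {
  read_epbd_parameters(system.file("extdata", "epbd_params_default.yaml",
                                   package = "epbdr", mustWork = TRUE),
                       canonical = canonical)
}

#' Resolve per-site model parameters for a sequence
#'
#' Maps each base pair of the sequence to its Morse constants (A·T or G·C
#' class) and each dinucleotide step (base n-1, base n) to its stacking
#' constant, producing the flat vectors the energy functions and the sampler
#' consume.
#'
#' @param seq A [dna_sequence()] (or plain base string).
#' @param params An [epbd_parameters()] object.
#' @return An `epbd_site_params` object: list with numeric vectors `D`, `a`
#'   (length N), `k_step` (length N-1, step i spans base pairs i and i+1),
#'   scalars `rho`, `b`, `kB`, `y_min_bound`, `y_max_bound`, and the base
#'   vector `bases`.
#' @export
resolve_site_parameters <- function(seq, params = default_parameters()) {
  if (!inherits(seq, "dna_sequence")) seq <- dna_sequence(seq)
  stopifnot(inherits(params, "epbd_parameters"))
  bases <- seq_bases(seq)
  cls <- ifelse(bases %in% c("A", "T"), "AT", "GC")
  n <- length(bases)
  steps <- paste0(bases[-n], bases[-1L])
  epbd_site_params(D = unname(params$morse_depth[cls]),
                   a = unname(params$morse_width[cls]),
                   k_step = unname(params$stacking_k[steps]),
                   rho = params$stacking_rho, b = params$stacking_b,
                   kB = params$kB,
                   y_min_bound = params$y_min_bound,
                   y_max_bound = params$y_max_bound,
                   bases = bases)
}

#' Construct per-site parameters directly
#'
#' Lower-level companion to [resolve_site_parameters()]: builds the per-site
#' parameter object from explicit vectors. This is the route for systems a
#' sequence object cannot express -- a single isolated base pair (`N = 1`,
#' empty `k_step`), or site-specific Morse perturbations emulating a lesion
#' or an SNP's local effect without changing the base identity.
#'
#' @param D,a Numeric vectors (length N) of Morse depths (eV) and inverse
#'   widths (1/Å).
#' @param k_step Numeric vector (length N-1) of stacking constants (eV/Å²).
#' @param rho,b Anharmonic stacking amplitude (dimensionless) and range (1/Å).
#' @param kB Boltzmann constant (eV/K).
#' @param y_min_bound,y_max_bound Displacement bounds (Å).
#' @param bases Optional base labels (length N), for outputs only.
#' @return An `epbd_site_params` object.
#' @export
epbd_site_params <- function(D, a, k_step, rho = 2, b = 0.35,
                             kB = 8.617333262e-5,
                             y_min_bound = -2, y_max_bound = 20,
                             bases = NULL) {
  n <- length(D)
  stopifnot(n >= 1L, length(a) == n, length(k_step) == n - 1L,
            all(D > 0), all(a > 0), all(k_step > 0) || n == 1L,
            rho >= 0, b >= 0, kB > 0, y_min_bound < 0, y_max_bound > 0)
  if (is.null(bases)) bases <- rep("N", n)
  structure(list(D = as.numeric(D), a = as.numeric(a),
                 k_step = as.numeric(k_step), rho = as.numeric(rho),
                 b = as.numeric(b), kB = as.numeric(kB),
                 y_min_bound = as.numeric(y_min_bound),
                 y_max_bound = as.numeric(y_max_bound),
                 bases = bases, n = n),
            class = "epbd_site_params")
}

#' @export
print.epbd_site_params <- function(x, ...) {
  cat(sprintf("<epbd_site_params> N=%d base pairs, %d stacking steps\n",
              x$n, length(x$k_step)))
  invisible(x)
}
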