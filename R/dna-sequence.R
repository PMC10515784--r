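#' Construct a DNA sequence object
#'
#' A light wrapper around a character string of bases. Input is
#' case-normalised to upper case and validated: only `A`, `C`, `G`, `T` are
#' allowed and at least two base pairs are required (so that one stacking
#' step exists).
#'
#' @param x A single character string of bases, or a character vector of
#'   single bases.
#' @param name Optional sequence name (e.g. a FASTA header).
#' @return An object of class `dna_sequence`: the upper-case base string,
#'   with attributes `name` and `n` (number of base pairs).
#' @examples
#' s <- dna_sequence("acgtACGT")
#' length(s)
#' @export
dna_sequence <- function(x, name = NULL) {
  if (is.character(x) && length(x) > 1L) x <- paste(x, collapse = "")
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(gsub("[[:space:]]", "", x))
  bases <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid base '%s' at position %d (alphabet is A/C/G/T)",
                 bases[bad[1L]], bad[1L]), call. = FALSE)
  }
  if (length(bases) < 2L) {
    stop("a DNA sequence needs at least 2 base pairs", call. = FALSE)
  }
  structure(x, class = "dna_sequence", name = name, n = length(bases))
}

#' @export
length.dna_sequence <- function(x) attr(x, "n")

#' @export
print.dna_sequence <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<dna_sequence> %d bp%s\n", attr(x, "n"),
              if (!is.null(nm)) paste0(" (", nm, ")") else ""))
  s <- unclass(x)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

seq_bases <- function(seq) strsplit(unclass(seq), "", fixed = TRUE)[[1L]]

#' Read a DNA sequence from a FASTA or plain-text file
#'
#' FASTA files are parsed with Biostrings; if the file holds more than one
#' record a warning is issued and the first record is used. Plain-text input
#' is whitespace-stripped and upper-cased. `format = "auto"` (the default)
#' treats files whose first non-blank character is `>` as FASTA.
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"`, `"fasta"`, `"text"`.
#' @return A [dna_sequence()] object. Positions are 1-based everywhere
#'   downstream.
#' @export
read_dna <- function(path, format = c("auto", "fasta", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("sequence file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0L) stop("empty sequence file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (startsWith(trimws(nonblank[1L]), ">")) "fasta" else "text"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
    if (length(set) > 1L) {
      warning(sprintf("%d FASTA records in %s; using the first ('%s')",
                      length(set), path, names(set)[1L]), call. = FALSE)
    }
    dna_sequence(as.character(set[[1L]]), name = names(set)[1L])
  } else {
    dna_sequence(paste(nonblank, collapse = ""), name = basename(path))
  }
}

#' Write a sequence to a FASTA file
#'
#' @param seq A [dna_sequence()] (or plain string).
#' @param path Output path.
#' @param name Record name; defaults to the sequence's `name` attribute.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path, name = NULL) {
  if (!inherits(seq, "dna_sequence")) seq <- dna_sequence(seq)
  name <- name %||% attr(seq, "name") %||% "seq"
  s <- unclass(seq)
  chunks <- substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59, nchar(s)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate deterministic test sequences
#'
#' Convenience generator for the sequence kinds used throughout the test
#' suite and examples: homopolymers, a promoter-like AT-rich fragment, and a
#' wild/mutant pair differing by a dinucleotide substitution (AG to TC at the
#' centre), emulating a two-adjacent-SNP allele pair.
#'
#' @param kind One of `"homoAT"`, `"homoGC"`, `"promoter_like"`, `"snp_pair"`.
#' @param length Sequence length in base pairs (>= 2; >= 4 for `snp_pair`).
#' @param seed Integer seed controlling the random kinds; the output is a
#'   deterministic function of `(kind, length, seed)`.
#' @param path Optional FASTA output path (for `snp_pair`, two files with
#'   suffixes `_wild.fa` and `_mutant.fa` are written next to `path`).
#' @return A [dna_sequence()], or for `"snp_pair"` a list with elements
#'   `wild` and `mutant` differing at exactly two adjacent positions.
#' @export
generate_fixture <- function(kind = c("homoAT", "homoGC", "promoter_like", "snp_pair"),
                             length = 60L, seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 2L) stop("length must be >= 2", call. = FALSE)
  mk <- function(chars, name) dna_sequence(paste(chars, collapse = ""), name = name)
  random_bases <- function(n, prob) {
    # local RNG; do not disturb the caller's stream
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
  }
  switch(kind,
    homoAT = mk(rep("A", length), sprintf("homoAT_%d", length)),
    homoGC = mk(rep("G", length), sprintf("homoGC_%d", length)),
    promoter_like = {
      # AT-rich core flanked by mixed sequence, loosely TATA-box-like
      b <- random_bases(length, prob = c(0.3, 0.2, 0.2, 0.3))
      core <- c("T", "A", "T", "A", "A", "T")
      at <- max(1L, length %/% 2L - 3L)
      idx <- at + seq_along(core) - 1L
      keep <- idx <= length
      b[idx[keep]] <- core[keep]
      s <- mk(b, sprintf("promoter_like_%d_seed%d", length, seed))
      if (!is.null(path)) write_fasta(s, path)
      s
    },
    snp_pair = {
      if (length < 4L) stop("snp_pair needs length >= 4", call. = FALSE)
      b <- random_bases(length, prob = c(0.3, 0.2, 0.2, 0.3))
      c0 <- length %/% 2L
      b[c0] <- "A"; b[c0 + 1L] <- "G"
      wild <- mk(b, sprintf("snp_wild_%d_seed%d", length, seed))
      bm <- b; bm[c0] <- "T"; bm[c0 + 1L] <- "C"
      mut <- mk(bm, sprintf("snp_mutant_%d_seed%d", length, seed))
      if (!is.null(path)) {
        stem <- sub("\\.fa(sta)?$", "", path)
        write_fasta(wild, paste0(stem, "_wild.fa"))
        write_fasta(mut, paste0(stem, "_mutant.fa"))
      }
      list(wild = wild, mutant = mut, positions = c(c0, c0 + 1L))
    })
}
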