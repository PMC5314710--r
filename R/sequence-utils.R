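#' mitoarch: control-region architecture of mitochondrial genomes
#'
#' See the package DESCRIPTION and the `control-region-architecture`
#' vignette for an overview of the pipeline: simulate or read annotated
#' mitogenomes, extract non-coding regions, scan for TAS/CSB motifs,
#' discover dispersed and tandem repeats, map region architecture, screen
#' gene orders, summarise genome sizes, and build codon supermatrices.
#'
#' @keywords internal
"_PACKAGE"

# Internal coordinate convention (all modules):
#   0-based half-open spans on a circular sequence of length L.
#   start in [0, L); end = start + length, NOT reduced mod L, so a span
#   wraps the origin iff end > L. Length is always end - start.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  # genome N matches nothing except pattern N (conservative: gap-filled
  # records must not yield phantom motif hits)
  N = c("A", "C", "G", "T", "N")
)

#' Generate random DNA
#'
#' I.i.d. background sequence with a given GC fraction.
#'
#' @param n length in bp
#' @param gc GC fraction in \[0, 1\]
#' @return a single DNA string over A/C/G/T
#' @export
random_dna <- function(n, gc = 0.45) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Handles IUPAC ambiguity codes; case is preserved as upper case.
#'
#' @param x DNA string
#' @return the reverse complement
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  fwd <- "ACGTRYSWKMBDHVN"
  rev <- "TGCAYRSWMKVHDBN"
  chartr(fwd, rev, paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

#' Basic composition statistics of a DNA string
#'
#' @param x DNA string
#' @return list with `length`, `gc` fraction (over unambiguous bases) and
#'   per-base `counts`
#' @export
dna_stats <- function(x) {
  ch <- strsplit(toupper(x), "")[[1]]
  counts <- table(factor(ch, levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(counts[c("A", "C", "G", "T")])
  list(
    length = nchar(x),
    gc = if (acgt > 0) unname((counts[["C"]] + counts[["G"]]) / acgt) else NA_real_,
    counts = counts
  )
}

# span length under the un-modded-end convention
span_length <- function(start, end) end - start

#' Extract a (possibly wrapping) span from a circular sequence
#'
#' Spans are 0-based half-open; `end > nchar(seq)` means the span wraps the
#' origin and the extraction concatenates suffix + prefix. This is the single
#' place where the wrapping convention is implemented.
#'
#' @param seq full circular sequence
#' @param start 0-based start in \[0, L)
#' @param end exclusive end, in (start, start + L\]
#' @return extracted string of length `end - start`
#' @export
extract_span <- function(seq, start, end) {
  L <- nchar(seq)
  stopifnot(start >= 0, start < L || (start == 0 && L == 0), end >= start, end - start <= L)
  if (end <= L) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, end - L))
}

# mismatch count between two equal-length strings (fast char compare)
str_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# identity fraction of two equal-length strings
str_identity <- function(a, b) {
  n <- nchar(a)
  if (n == 0) return(NA_real_)
  1 - str_mismatches(a, b) / n
}
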