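#' IUPAC nucleotide code table
#'
#' Mapping from each IUPAC degenerate nucleotide code to the set of concrete
#' bases it denotes.
#'
#' @return A named list of character vectors; names are the 15 IUPAC codes.
#' @examples
#' iupac_codes()[["N"]]
#' @export
iupac_codes <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

assert_iupac <- function(x, arg = "sequence") {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% names(iupac_codes()))
  if (length(bad) > 0) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], arg), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

#' Replace degenerate IUPAC codes with concrete bases
#'
#' A synthetic molecule must carry concrete bases where a primer contains
#' degenerate codes. Each degenerate code is replaced by one member of its
#' class under a fixed, documented policy so the substitution is reproducible.
#'
#' @param primer Primer sequence, possibly containing IUPAC degenerate codes.
#' @param policy Substitution policy. `"first-of-class"` (default) picks the
#'   alphabetically first base (A < C < G < T) of each code's class.
#' @return A concrete `ACGT` string of the same length. Idempotent on
#'   already-concrete input.
#' @examples
#' concretize_primer("GGNGACTGGGACTTCTGG")
#' @export
concretize_primer <- function(primer, policy = "first-of-class") {
  stopifnot(length(primer) == 1, is.character(primer))
  policy <- match.arg(policy, "first-of-class")
  seq <- assert_iupac(primer, "primer")
  codes <- iupac_codes()
  chars <- strsplit(seq, "")[[1]]
  out <- vapply(chars, function(ch) sort(codes[[ch]])[1], character(1))
  paste(out, collapse = "")
}

#' Reverse complement of a (possibly degenerate) nucleotide sequence
#'
#' @param x Nucleotide string over the IUPAC alphabet.
#' @return The reverse complement, preserving degenerate codes.
#' @examples
#' revcomp("GACTACHVGGGTATCTAATCC")
#' @export
revcomp <- function(x) {
  x <- assert_iupac(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of a concrete nucleotide sequence
#'
#' @param sequence Nucleotide string over `{A,C,G,T}`.
#' @return Fraction of G + C bases, in `[0, 1]`.
#' @examples
#' gc_content("GCGC")
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("gc_content: empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("gc_content: sequence must be concrete A/C/G/T", call. = FALSE)
  }
  sum(chars %in% c("G", "C")) / length(chars)
}

# Hamming-style mismatch count of an IUPAC primer against an equal-length
# concrete window: a position matches when the window base is in the code's
# class.
iupac_mismatches <- function(primer_chars, window_chars, codes = iupac_codes()) {
  sum(!mapply(function(p, w) w %in% codes[[p]], primer_chars, window_chars))
}
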