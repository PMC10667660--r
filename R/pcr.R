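# IUPAC-aware scanning of one primer against one strand of a concrete
# template. Returns plus-strand 1-based inclusive coordinates.
scan_one_strand <- function(primer, template, max_mismatch, strand) {
  if (nchar(primer) > nchar(template)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), mismatches = integer()))
  }
  subj <- if (strand == "+") template else revcomp(template)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer), Biostrings::DNAString(subj),
    max.mismatch = max_mismatch, with.indels = FALSE, fixed = FALSE
  )
  if (length(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), mismatches = integer()))
  }
  s <- BiocGenerics::start(hits)
  e <- BiocGenerics::end(hits)
  pchars <- strsplit(primer, "")[[1]]
  mm <- vapply(seq_along(s), function(i) {
    win <- strsplit(substr(subj, s[i], e[i]), "")[[1]]
    as.integer(iupac_mismatches(pchars, win))
  }, integer(1))
  if (strand == "-") {
    L <- nchar(template)
    tmp <- s
    s <- L - e + 1L
    e <- L - tmp + 1L
  }
  ord <- order(s)
  tibble::tibble(start = as.integer(s[ord]), end = as.integer(e[ord]),
                 strand = strand, mismatches = mm[ord])
}

#' Screen a sequence for unintended primer matches
#'
#' Slides every primer of the panel over both strands of `sequence`
#' (IUPAC-aware: a degenerate code matches any base of its class) and reports
#' every hit with at most `max_mismatch` mismatches whose footprint is not
#' fully contained in the union of the whitelisted layout sites. An empty
#' result means the sequence passes.
#'
#' @param sequence Concrete template sequence.
#' @param primers Primer-set tibble (see [primer_set()]).
#' @param allowed_sites Layout tibble with `start`/`end` columns of declared
#'   primer sites; `NULL` whitelists nothing.
#' @param max_mismatch Mismatch tolerance (default 2).
#' @return Tibble of violations: `primer`, `strand`, `start`, `end`,
#'   `mismatches`.
#' @export
screen_primer_matches <- function(sequence, primers, allowed_sites = NULL,
                                  max_mismatch = 2) {
  stopifnot(max_mismatch >= 0)
  if (nchar(sequence) == 0 || nrow(primers) == 0) {
    return(tibble::tibble(primer = character(), strand = character(),
                          start = integer(), end = integer(),
                          mismatches = integer()))
  }
  sequence <- toupper(sequence)
  panel <- dplyr::bind_rows(
    tibble::tibble(primer = primers$forward_name, seq = primers$forward),
    tibble::tibble(primer = primers$reverse_name, seq = primers$reverse)
  )
  panel <- dplyr::distinct(panel)
  hits <- purrr::pmap_dfr(panel, function(primer, seq) {
    dplyr::bind_rows(
      scan_one_strand(seq, sequence, max_mismatch, "+"),
      scan_one_strand(seq, sequence, max_mismatch, "-")
    ) |> dplyr::mutate(primer = primer, .before = 1)
  })
  if (nrow(hits) == 0 || is.null(allowed_sites) || nrow(allowed_sites) == 0) {
    return(hits)
  }
  covered <- rep(FALSE, nchar(sequence))
  for (i in seq_len(nrow(allowed_sites))) {
    covered[allowed_sites$start[i]:allowed_sites$end[i]] <- TRUE
  }
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    !all(covered[hits$start[i]:hits$end[i]])
  }, logical(1))
  hits[keep, , drop = FALSE]
}

#' In-silico PCR with degenerate primers
#'
#' Finds forward-primer binding sites on the plus strand and reverse-primer
#' sites on the minus strand (the reverse primer is matched against the
#' reverse complement) and reports every product whose reverse site ends
#' downstream of the forward site. Product length is counted inclusive of
#' both primer binding sites; coordinates are 1-based inclusive.
#'
#' @param template Concrete template sequence (or a named character vector of
#'   templates, in which case a `template` column is added).
#' @param forward,reverse Primer sequences 5'-3', IUPAC codes allowed.
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return Tibble with `start`, `end`, `length`, `sequence` (one row per
#'   product; zero rows when either primer does not bind).
#' @examples
#' tpl <- paste0("GGAGACTGGGACTTCTGG", strrep("A", 5),
#'               revcomp("ACGTCCTTACCGAAGGT"))
#' insilico_pcr(tpl, "GGNGACTGGGACTTCTGG", "ACGTCCTTACCGAAGGT")
#' @export
insilico_pcr <- function(template, forward, reverse, max_mismatch = 0) {
  if (length(template) > 1) {
    nms <- names(template) %||% as.character(seq_along(template))
    return(purrr::map2_dfr(template, nms, function(t, n) {
      dplyr::mutate(insilico_pcr(t, forward, reverse, max_mismatch),
                    template = n, .before = 1)
    }))
  }
  template <- toupper(template)
  forward <- assert_iupac(forward, "forward primer")
  reverse <- assert_iupac(reverse, "reverse primer")
  if (nchar(template) < nchar(forward) + nchar(reverse)) {
    stop("template shorter than the two primers combined", call. = FALSE)
  }
  fwd <- scan_one_strand(forward, template, max_mismatch, "+")
  rev <- scan_one_strand(reverse, template, max_mismatch, "-")
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer(), sequence = character()))
  }
  prods <- tidyr::crossing(
    f_start = fwd$start,
    r_end = rev$end
  )
  f_len <- nchar(forward)
  prods <- dplyr::filter(prods, .data$r_end >= .data$f_start + f_len +
                           nchar(reverse) - 1)
  tibble::tibble(
    start = as.integer(prods$f_start),
    end = as.integer(prods$r_end),
    length = as.integer(prods$r_end - prods$f_start + 1L),
    sequence = substring(template, prods$f_start, prods$r_end)
  ) |> dplyr::arrange(.data$start, .data$end)
}
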