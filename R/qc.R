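#' Read recovery ratio of a processing pipeline
#'
#' Fraction of reads surviving denoising: reads out of the pipeline divided
#' by reads into it.
#'
#' @param read_in,read_out Read counts before and after processing.
#' @return `read_out / read_in`, vectorized.
#' @export
read_recovery_ratio <- function(read_in, read_out) {
  if (any(read_in <= 0)) stop("read_in must be > 0", call. = FALSE)
  if (any(read_out < 0) || any(read_out > read_in)) {
    stop("read_out must be in [0, read_in]", call. = FALSE)
  }
  read_out / read_in
}

#' Single-end vs. paired-end recovery increment factor
#'
#' Fold change of the single-end-forward read recovery ratio over the
#' paired-end one; computed per category (ISG vs. biological) it exposes
#' category-differential read loss during merging/denoising.
#'
#' @param se_ratio,pe_ratio Recovery ratios of the SE-R1 and PE pipelines.
#' @return `se_ratio / pe_ratio`, vectorized.
#' @export
increment_factor <- function(se_ratio, pe_ratio) {
  if (any(pe_ratio <= 0)) stop("pe_ratio must be > 0", call. = FALSE)
  se_ratio / pe_ratio
}

#' Label ASVs as internal standard, biological or discard
#'
#' An ASV is labelled `ISG` when its sequence is identical to a reference
#' standard over the compared length (references are truncated to
#' `read_length` for single-end data); same-length sequences within
#' `max_mismatch` mismatches of a reference are sequencing artefacts of the
#' standards and labelled `discard`; everything else is `biological`.
#'
#' @param asv_table Data frame with `asv_id` and `sequence` columns.
#' @param references Named character vector of ISG reference sequences (or
#'   anything coercible; names become reference ids).
#' @param read_length Compared length in bp (`NULL` compares full length).
#' @param max_mismatch Near-match radius for the discard rule (default 2).
#' @return The table with added `label` and `matched_ref` columns.
#' @export
partition_isg_reads <- function(asv_table, references, read_length = NULL,
                                max_mismatch = 2) {
  stopifnot(all(c("asv_id", "sequence") %in% names(asv_table)))
  if (length(references) == 0) stop("references must be non-empty", call. = FALSE)
  if (anyDuplicated(asv_table$asv_id)) {
    stop("duplicate asv_id in input table", call. = FALSE)
  }
  refs <- toupper(as.character(references))
  names(refs) <- names(references) %||% paste0("ref", seq_along(refs))
  if (!is.null(read_length)) {
    refs <- substr(refs, 1, read_length)
  }
  classify <- function(seq) {
    seq <- toupper(seq)
    same_len <- refs[nchar(refs) == nchar(seq)]
    if (length(same_len) == 0) {
      return(c("biological", NA_character_))
    }
    d <- vapply(same_len, function(r) {
      sum(strsplit(r, "")[[1]] != strsplit(seq, "")[[1]])
    }, numeric(1))
    j <- which.min(d)
    if (d[j] == 0) c("ISG", names(same_len)[j])
    else if (d[j] <= max_mismatch) c("discard", names(same_len)[j])
    else c("biological", NA_character_)
  }
  res <- vapply(asv_table$sequence, classify, character(2), USE.NAMES = FALSE)
  dplyr::mutate(tibble::as_tibble(asv_table),
                label = res[1, ], matched_ref = res[2, ])
}

#' GGC trinucleotide profile of an amplicon
#'
#' Counts every (overlap-aware) occurrence of the GGC motif on the sense
#' strand and partitions occurrences by start position relative to a
#' boundary - by default 251 bp, the extent of a single-end forward read, so
#' `n_behind` counts motifs in the region only reached by the reverse read.
#'
#' @param sequence Amplicon sequence (sense strand).
#' @param boundary Position boundary in bp (default 251).
#' @return Tibble with `total`, `n_front`, `n_behind`, `boundary`.
#' @export
ggc_profile <- function(sequence, boundary = 251) {
  stopifnot(boundary >= 0)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  starts <- integer(0)
  if (n >= 3) {
    for (i in 1:(n - 2)) {
      if (substr(sequence, i, i + 2) == "GGC") starts <- c(starts, i)
    }
  }
  tibble::tibble(
    total = length(starts),
    n_front = sum(starts <= boundary),
    n_behind = sum(starts > boundary),
    boundary = as.integer(boundary)
  )
}

#' Amplicon GC-content table for templates against a primer panel
#'
#' Runs in-silico PCR for every (template, primer set) combination and
#' reports the product length and GC fraction; combinations without a
#' product yield a row with `NA` length and GC.
#'
#' @param templates Named character vector of template sequences.
#' @param primer_sets Primer-set tibble (see [primer_set()]).
#' @param max_mismatch Mismatches tolerated per primer site.
#' @return Tibble: `template`, `primer_set`, `amplicon_length`,
#'   `gc_fraction` (one row per product, or one `NA` row).
#' @export
amplicon_gc_table <- function(templates, primer_sets = isg_primer_sets(),
                              max_mismatch = 0) {
  if (length(templates) == 0) stop("need at least one template", call. = FALSE)
  nms <- names(templates) %||% paste0("template", seq_along(templates))
  combos <- tidyr::crossing(template = nms, primer_set = primer_sets$name)
  purrr::pmap_dfr(combos, function(template, primer_set) {
    ps <- primer_sets[primer_sets$name == primer_set, ]
    prods <- tryCatch(
      insilico_pcr(unname(templates[[template]]), ps$forward, ps$reverse,
                   max_mismatch),
      error = function(e) tibble::tibble()
    )
    if (nrow(prods) == 0) {
      tibble::tibble(template = template, primer_set = primer_set,
                     amplicon_length = NA_integer_, gc_fraction = NA_real_)
    } else {
      tibble::tibble(template = template, primer_set = primer_set,
                     amplicon_length = prods$length,
                     gc_fraction = vapply(prods$sequence, gc_content,
                                          numeric(1), USE.NAMES = FALSE))
    }
  })
}
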