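#' Construct a primer-set table
#'
#' A primer set is a named degenerate primer pair together with the expected
#' amplicon length (inclusive of both primer binding sites).
#'
#' @param name Label for the pair (e.g. `"pmoA_189f/650r"`).
#' @param forward,reverse Primer sequences 5'-3', IUPAC codes allowed.
#' @param forward_name,reverse_name Individual primer names; reverse primers
#'   shared between pairs (such as 805R) must reuse the same name.
#' @param target_gene Marker gene label.
#' @param expected_amplicon_len Expected product length in bp.
#' @return A one-row tibble; rows from several calls can be bound together.
#' @examples
#' primer_set("16S_515F/805R", "GTGCCAGCMGCCGCGGTAA", "GACTACHVGGGTATCTAATCC",
#'            "515F", "805R", "16S rRNA", 291)
#' @export
primer_set <- function(name, forward, reverse, forward_name, reverse_name,
                       target_gene, expected_amplicon_len) {
  forward <- assert_iupac(forward, "forward primer")
  reverse <- assert_iupac(reverse, "reverse primer")
  expected_amplicon_len <- as.integer(expected_amplicon_len)
  if (expected_amplicon_len < nchar(forward) + nchar(reverse)) {
    stop("expected_amplicon_len shorter than the two primers combined",
         call. = FALSE)
  }
  tibble::tibble(
    name = name, forward = forward, reverse = reverse,
    forward_name = forward_name, reverse_name = reverse_name,
    target_gene = target_gene,
    expected_amplicon_len = expected_amplicon_len
  )
}

#' The default multi-marker primer panel
#'
#' The five primer pairs carried by the internal-standard genes: two pmoA
#' pairs (189f with 650r or 682r), the Nitrosomonadaceae amoA 1F/2R pair and
#' the 16S rRNA V3-V4 (341F/805R) and V4 (515F/805R) pairs. 805R is shared
#' between the two 16S pairs and 189f between the two pmoA pairs.
#'
#' @return A five-row primer-set tibble (see [primer_set()]).
#' @examples
#' isg_primer_sets()
#' @export
isg_primer_sets <- function() {
  dplyr::bind_rows(
    primer_set("pmoA_189f/650r", "GGNGACTGGGACTTCTGG", "ACGTCCTTACCGAAGGT",
               "pmoA_189f", "pmoA_650r", "pmoA", 500L),
    primer_set("pmoA_189f/682r", "GGNGACTGGGACTTCTGG", "GAASGCNGAGAAGAASGC",
               "pmoA_189f", "pmoA_682r", "pmoA", 531L),
    primer_set("amoA_1F/2R", "GGGGTTTCTACTGGTGGT", "CCCCTCKGSAAAGCCTTCTTC",
               "amoA_1F", "amoA_2R", "amoA", 491L),
    primer_set("16S_341F/805R", "CCTACGGGNGGCWGCAG", "GACTACHVGGGTATCTAATCC",
               "16S_341F", "16S_805R", "16S rRNA", 465L),
    primer_set("16S_515F/805R", "GTGCCAGCMGCCGCGGTAA", "GACTACHVGGGTATCTAATCC",
               "16S_515F", "16S_805R", "16S rRNA", 291L)
  )
}
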