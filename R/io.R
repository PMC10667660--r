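#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings with the package's conventions: sequences
#' are upper-cased on read, ids are the full description line, and an empty
#' file yields an empty vector with a warning.
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(toupper(sequences))
  names(set) <- names(sequences) %||% paste0("seq", seq_along(sequences))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an ASV count table
#'
#' Tab-separated text with at least `asv_id` and `reads` columns (plus
#' whatever else the caller carries, e.g. `sequence`, `sample_id`, `label`);
#' extra columns pass through untouched.
#'
#' @param path File path.
#' @param required Columns that must be present.
#' @return A tibble.
#' @export
read_asv_table <- function(path, required = c("asv_id", "reads")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("ASV table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$reads < 0)) stop("negative read counts in table", call. = FALSE)
  tab
}

#' Write a quantified ASV table
#'
#' Tab-separated, full-precision numbers, LOQ flags as TRUE/FALSE.
#'
#' @param quant An `isg_quant` object or its `table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  tab <- if (inherits(quant, "isg_quant")) quant$table else quant
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Run the spike-in quantification pipeline
#'
#' Partition (when sequences and references are supplied), calibrate,
#' quantify and report: writes the quantified ASV table, a curve report and
#' a machine-readable run manifest (inputs hash, seed, package version)
#' under `output_dir`.
#'
#' @param asv_table Data frame or path to a TSV with `asv_id`, `reads` and
#'   either a `label` column (with `variant_id`/`level` on ISG rows) or a
#'   `sequence` column to be partitioned against `references`.
#' @param spike A [spikein_series()]; when partitioning, ISG reference names
#'   must match its `variant_id` values.
#' @param references Optional named character vector of ISG reference
#'   sequences for partitioning.
#' @param read_length Compared length for partitioning (see
#'   [partition_isg_reads()]).
#' @param factors,sample Volume chain and sample factors.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, a list with the `isg_quant` object and output paths.
#' @export
run_pipeline <- function(asv_table, spike = default_spikein_gradient(),
                         references = NULL, read_length = NULL,
                         factors = conversion_factors(),
                         sample = sample_factors(),
                         output_dir = "isgquant-out", seed = 1) {
  if (is.character(asv_table) && length(asv_table) == 1) {
    asv_table <- read_asv_table(asv_table)
  }
  n_discarded <- 0L
  if (!"label" %in% names(asv_table)) {
    if (is.null(references)) {
      stop("pipeline aborted at partition: no label column and no references",
           call. = FALSE)
    }
    asv_table <- partition_isg_reads(asv_table, references, read_length)
    n_discarded <- sum(asv_table$label == "discard")
    asv_table <- dplyr::filter(asv_table, .data$label != "discard")
    # one gradient level per variant: map matched reference -> spike design
    lv <- dplyr::distinct(tibble::as_tibble(spike),
                          .data$variant_id, .data$level)
    if (anyDuplicated(lv$variant_id)) {
      stop("pipeline aborted at partition: spike design has several levels per variant; supply explicit ISG labels",
           call. = FALSE)
    }
    asv_table <- asv_table |>
      dplyr::mutate(variant_id = ifelse(.data$label == "ISG",
                                        .data$matched_ref, NA_character_)) |>
      dplyr::left_join(lv, by = "variant_id")
  }
  quant <- quantify_asvs(asv_table, spike, factors, sample)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    quant_table = file.path(output_dir, "asv_quant.tsv"),
    curve = file.path(output_dir, "curve_report.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_quant_table(quant, paths$quant_table)
  readr::write_tsv(glance(quant$curve), paths$curve, progress = FALSE)
  manifest <- list(
    package = "isgquant",
    version = as.character(utils::packageVersion("isgquant")),
    seed = seed,
    n_asvs = nrow(asv_table),
    n_discarded = n_discarded,
    loq_reads = as.numeric(quant$loq),
    total_conc_dna = quant$total_conc_dna,
    input_hash = rlang::hash(list(asv_table, tibble::as_tibble(spike),
                                  unclass(factors), unclass(sample)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(quant = quant, paths = paths))
}
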