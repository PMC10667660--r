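#' Configuration of a synthetic spike-in experiment
#'
#' Bundles everything that determines a simulated amplicon library: the
#' spike-in design, the biological community with per-taxon amplification
#' efficiencies, the detection efficiency (reads per copy, the `exp(b)` of
#' the dose-response model), the NB dispersion, and the volume chain.
#'
#' Defaults emulate the study conditions of the recovery analyses: four ISG
#' variants observed along the full four-level gradient (16 calibration
#' points), detection efficiency 8 reads/copy, NB size 5, and an equimolar
#' community of 12 taxa at 3.0e4 copies/uL DNA (a mock-community-style
#' design at the mock standard concentration).
#'
#' @param spike A [spikein_series()].
#' @param taxa Tibble with `taxon_id`, `conc_dna` (copies/uL DNA) and
#'   `efficiency` (relative amplification efficiency in `(0, 1]`).
#' @param detection_efficiency Reads per copy per uL reaction (> 0).
#' @param dispersion NB size parameter (> 0); `Inf` gives Poisson counts.
#' @param factors A [conversion_factors()] object.
#' @param sample A [sample_factors()] object.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(spike = crossed_spikein_series(),
                              taxa = tibble::tibble(
                                taxon_id = sprintf("taxon%02d", 1:12),
                                conc_dna = 3.0e4,
                                efficiency = 1),
                              detection_efficiency = 8,
                              dispersion = 5,
                              factors = conversion_factors(),
                              sample = sample_factors()) {
  stopifnot(detection_efficiency > 0, dispersion > 0)
  if (nrow(taxa) > 0) {
    stopifnot(all(taxa$efficiency > 0), all(taxa$efficiency <= 1),
              all(taxa$conc_dna > 0))
  }
  structure(list(spike = spike, taxa = taxa,
                 detection_efficiency = detection_efficiency,
                 dispersion = dispersion, factors = factors,
                 sample = sample),
            class = "sim_config")
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a spike-in amplicon library with known truth
#'
#' Draws NB read counts for every internal-standard (variant, level) row and
#' every biological taxon. Expected reads are
#' `mu = detection_efficiency * efficiency * conc_reaction`, with in-reaction
#' concentrations derived through the volume chain ([isg_reaction_conc()]
#' for standards, [expected_reaction_conc()] for taxa).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical (config, seed) give byte-identical
#'   libraries.
#' @return List of class `isg_sim`: `asv_table` (ready for
#'   [quantify_asvs()]), `truth` (per-row expected reads and true
#'   concentrations) and the `config`.
#' @export
simulate_library <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  doses <- isg_reaction_conc(config$spike, config$factors)
  isg <- doses |>
    dplyr::mutate(
      asv_id = sprintf("%s_L%g", .data$variant_id, .data$level),
      label = "ISG",
      mu = config$detection_efficiency * .data$conc_reaction
    )
  taxa <- config$taxa
  bio <- if (nrow(taxa) > 0) {
    taxa |>
      dplyr::mutate(
        asv_id = .data$taxon_id,
        label = "biological",
        conc_reaction = expected_reaction_conc(.data$conc_dna,
                                               config$factors, TRUE),
        mu = config$detection_efficiency * .data$efficiency *
          .data$conc_reaction
      )
  } else NULL

  withr::with_seed(seed, {
    isg$reads <- rnb(nrow(isg), isg$mu, config$dispersion)
    if (!is.null(bio)) {
      bio$reads <- rnb(nrow(bio), bio$mu, config$dispersion)
    }
  })

  asv_table <- dplyr::bind_rows(
    dplyr::select(isg, "asv_id", "reads", "label", "variant_id", "level"),
    if (!is.null(bio)) {
      dplyr::transmute(bio, asv_id = .data$asv_id, reads = .data$reads,
                       label = .data$label, variant_id = NA_character_,
                       level = NA_real_)
    }
  )
  truth <- dplyr::bind_rows(
    dplyr::select(isg, "asv_id", "label", "conc_reaction",
                  expected_reads = "mu"),
    if (!is.null(bio)) {
      dplyr::select(bio, "asv_id", "label", "conc_dna", "efficiency",
                    "conc_reaction", expected_reads = "mu")
    }
  )
  structure(list(asv_table = asv_table, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "isg_sim")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate mock "genomic" templates with planted amplicons
#'
#' Emits one synthetic template per taxon: a random backbone carrying a
#' primer-flanked amplicon for the taxon's primer set, plus a truth table of
#' copies per uL. Together with designed ISGs these serve as end-to-end
#' fixtures for in-silico PCR, partitioning and quantification.
#'
#' @param n_taxa Number of mock taxa (0 gives an ISG-only fixture).
#' @param conc Copies per uL of each taxon (scalar or vector).
#' @param primer_sets Primer-set tibble; taxa cycle through its rows.
#' @param flank Length of random flanking sequence either side.
#' @param seed Integer seed.
#' @return List: `templates` (named character), `truth` (tibble with
#'   `taxon_id`, `conc`, `primer_set`).
#' @export
simulate_mock_references <- function(n_taxa = 3, conc = 3.0e4,
                                     primer_sets = isg_primer_sets(),
                                     flank = 60, seed = 1) {
  conc <- rep_len(conc, max(n_taxa, 1))
  withr::with_seed(seed, {
    templates <- character(0)
    rows <- list()
    for (i in seq_len(n_taxa)) {
      ps <- primer_sets[((i - 1) %% nrow(primer_sets)) + 1, ]
      insert_len <- ps$expected_amplicon_len - nchar(ps$forward) -
        nchar(ps$reverse)
      tpl <- NULL
      for (try in 1:25) {
        amplicon <- paste0(concretize_primer(ps$forward),
                           random_bases(insert_len),
                           revcomp(concretize_primer(ps$reverse)))
        cand <- paste0(random_bases(flank), amplicon, random_bases(flank))
        prods <- insilico_pcr(cand, ps$forward, ps$reverse)
        if (nrow(prods) == 1 && prods$length == ps$expected_amplicon_len) {
          tpl <- cand
          break
        }
      }
      if (is.null(tpl)) {
        stop("could not construct a clean mock template", call. = FALSE)
      }
      id <- sprintf("mock%02d", i)
      templates[[id]] <- tpl
      rows[[i]] <- tibble::tibble(taxon_id = id, conc = conc[i],
                                  primer_set = ps$name)
    }
    list(templates = templates,
         truth = if (n_taxa > 0) dplyr::bind_rows(rows) else
           tibble::tibble(taxon_id = character(), conc = numeric(),
                          primer_set = character()))
  })
}
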