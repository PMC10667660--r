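#' Convert a DNA mass concentration to copy numbers
#'
#' Copies per microlitre of a fragment of known length from its mass
#' concentration: `C = M * 6.02e23 / (660 * 1e9 * L)`, with 660 g/mol/bp as
#' the mean molar mass of a double-stranded base pair.
#'
#' @param mass_conc Mass concentration in ng/uL.
#' @param dna_length Fragment length in bp.
#' @return Copies per uL.
#' @examples
#' mass_to_copies(1, 615)
#' @export
mass_to_copies <- function(mass_conc, dna_length) {
  if (any(dna_length <= 0)) stop("dna_length must be > 0", call. = FALSE)
  if (any(mass_conc < 0)) stop("mass_conc must be >= 0", call. = FALSE)
  mass_conc * 6.02e23 / (660 * 1e9 * dna_length)
}

#' Volume factors of the template-preparation chain
#'
#' The multiplicative chain linking a concentration in extracted DNA to the
#' concentration in the PCR reaction: sample dilution (`D` uL of DNA brought
#' to `E` uL), mixing with the internal standard (`F` uL of diluted sample in
#' a `G` uL sample+ISG mix) and templating (`H` uL of the mix in an `I` uL
#' reaction). Defaults reflect undiluted extracts mixed 3:1 with ISGs and
#' 2.5 uL template in a 50 uL reaction.
#'
#' @param D,E,F,G,H,I Volumes in uL; all positive, `D <= E`, `F <= G`,
#'   `H <= I`.
#' @return A list of class `conversion_factors`.
#' @export
conversion_factors <- function(D = 1, E = 1, F = 3, G = 4, H = 2.5, I = 50) {
  v <- c(D = D, E = E, F = F, G = G, H = H, I = I)
  if (any(v <= 0)) stop("all volumes must be > 0", call. = FALSE)
  if (D > E || F > G || H > I) {
    stop("require D <= E, F <= G and H <= I", call. = FALSE)
  }
  structure(as.list(v), class = "conversion_factors")
}

#' Sample-level factors for per-gram or per-litre reporting
#'
#' @param extraction_vol DNA extract volume `C` in uL.
#' @param sample_amount Sample amount `A` (weight or volume).
#' @param unit Unit of `sample_amount`: `"g"` or `"L"`.
#' @return A list of class `sample_factors`.
#' @export
sample_factors <- function(extraction_vol = 100, sample_amount = 0.2,
                           unit = c("g", "L")) {
  unit <- match.arg(unit)
  if (extraction_vol <= 0 || sample_amount <= 0) {
    stop("extraction_vol and sample_amount must be > 0", call. = FALSE)
  }
  structure(list(extraction_vol = extraction_vol,
                 sample_amount = sample_amount, unit = unit),
            class = "sample_factors")
}

#' Expected in-reaction concentration of a template
#'
#' Forward direction of the volume chain:
#' `Z = conc * (D/E) * (F/G if include_sample_mix) * (H/I)`. With
#' `include_sample_mix = FALSE` the chain matches a template added to the
#' reaction without the sample+ISG mixing step (the qPCR variant).
#'
#' @param conc Concentration in copies/uL (of extracted DNA, or of the
#'   solution entering the chain).
#' @param factors A [conversion_factors()] object.
#' @param include_sample_mix Apply the `F/G` sample-mix term? Default `TRUE`.
#' @return Copies per uL of reaction.
#' @export
expected_reaction_conc <- function(conc, factors = conversion_factors(),
                                   include_sample_mix = TRUE) {
  z <- conc * (factors$D / factors$E) * (factors$H / factors$I)
  if (include_sample_mix) z <- z * (factors$F / factors$G)
  z
}

#' Invert the volume chain: reaction concentration back to DNA concentration
#'
#' Exact inverse of [expected_reaction_conc()]:
#' `Y = z * (E/D) * (G/F if include_sample_mix) * (I/H)`.
#'
#' @param z Copies per uL of reaction.
#' @inheritParams expected_reaction_conc
#' @return Copies per uL of extracted DNA.
#' @export
reaction_to_dna_conc <- function(z, factors = conversion_factors(),
                                 include_sample_mix = TRUE) {
  y <- z * (factors$E / factors$D) * (factors$I / factors$H)
  if (include_sample_mix) y <- y * (factors$G / factors$F)
  y
}

#' Concentration per unit of original sample
#'
#' `X = Y * C / A` with `C` the extract volume and `A` the sample weight or
#' volume; assumes 100% DNA extraction efficiency unless `efficiency` is set.
#'
#' @param y Copies per uL of extracted DNA.
#' @param sample A [sample_factors()] object.
#' @param efficiency Assumed DNA extraction efficiency in `(0, 1]`.
#' @return Copies per g or per L, according to `sample$unit`.
#' @export
dna_to_sample_conc <- function(y, sample = sample_factors(), efficiency = 1) {
  stopifnot(efficiency > 0, efficiency <= 1)
  y * sample$extraction_vol / (sample$sample_amount * efficiency)
}

#' Detection efficiency: reads per template copy
#'
#' @param reads Read count.
#' @param copies Template amount in copies/uL-reaction; must be positive.
#' @return Reads per copy.
#' @export
detection_efficiency <- function(reads, copies) {
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  reads / copies
}
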