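#' Construct a spike-in standard series
#'
#' Describes the mixed internal-standard solution added to each sample: one
#' row per (variant, gradient level) with the concentration that solution
#' contributes to the final mixed standard.
#'
#' @param variant_id Character vector of ISG variant ids.
#' @param level Gradient level of each row, in copies/uL before mixing.
#' @param conc Contribution of each row to the mixed standard, copies/uL.
#' @return Tibble of class `spikein_series` with attribute `total_conc`.
#' @export
spikein_series <- function(variant_id, level, conc) {
  if (length(conc) == 0) stop("empty spike-in series", call. = FALSE)
  if (any(conc <= 0) || any(level <= 0)) {
    stop("spike-in concentrations must be > 0", call. = FALSE)
  }
  out <- tibble::tibble(variant_id = variant_id, level = level, conc = conc)
  attr(out, "total_conc") <- sum(conc)
  class(out) <- c("spikein_series", class(out))
  out
}

#' Build a gradient spike-in series by dilution and equal-volume mixing
#'
#' Each variant is diluted from a common stock by its own factor, then all
#' solutions are combined in equal volumes, so each contributes its diluted
#' concentration divided by the number of solutions mixed.
#'
#' @param stock_conc Common stock concentration in copies/uL.
#' @param dilution_factors One dilution factor per variant (> 0).
#' @param variant_id Variant ids; defaults to `ISG01`, `ISG02`, ...
#' @return A [spikein_series()]; `attr(x, "total_conc")` is the total
#'   standard concentration of the mix.
#' @examples
#' s <- build_spikein_series(4.0e8, c(100, 1e3, 1e4, 1e5))
#' attr(s, "total_conc")  # 1.111e6 copies/uL
#' @export
build_spikein_series <- function(stock_conc, dilution_factors,
                                 variant_id = sprintf("ISG%02d",
                                   seq_along(dilution_factors))) {
  if (length(dilution_factors) == 0) {
    stop("empty dilution series", call. = FALSE)
  }
  if (stock_conc <= 0 || any(dilution_factors <= 0)) {
    stop("stock and dilution factors must be > 0", call. = FALSE)
  }
  level <- stock_conc / dilution_factors
  spikein_series(variant_id, level, level / length(level))
}

#' The default four-variant gradient standard
#'
#' Four ISG variants diluted to 4.0e6, 4.0e5, 4.0e4 and 4.0e3 copies/uL and
#' mixed in equal volumes (total 1.111e6 copies/uL).
#'
#' @return A [spikein_series()].
#' @export
default_spikein_gradient <- function() {
  build_spikein_series(4.0e8, c(100, 1e3, 1e4, 1e5))
}

#' Spike-in design with a full gradient per variant
#'
#' Crosses every variant with every gradient level, as used for simulation
#' studies where each variant is observed along the whole dose range; all
#' solutions are mixed in equal volumes.
#'
#' @param n_variants Number of ISG variants.
#' @param levels Gradient concentrations in copies/uL before mixing.
#' @return A [spikein_series()] with `n_variants * length(levels)` rows.
#' @export
crossed_spikein_series <- function(n_variants = 4,
                                   levels = c(4.0e6, 4.0e5, 4.0e4, 4.0e3)) {
  des <- tidyr::crossing(
    variant_id = sprintf("ISG%02d", seq_len(n_variants)),
    level = levels
  )
  spikein_series(des$variant_id, des$level, des$level / nrow(des))
}

#' In-reaction concentration of the spiked standards
#'
#' The internal standards enter the template as the ISG share of the
#' sample+ISG mixture, i.e. scaled by `(G - F)/G`, then by the templating
#' ratio `H/I`.
#'
#' @param spike A [spikein_series()].
#' @param factors A [conversion_factors()] object.
#' @return The series with an added `conc_reaction` column (copies per uL of
#'   reaction).
#' @export
isg_reaction_conc <- function(spike, factors = conversion_factors()) {
  isg_fraction <- (factors$G - factors$F) / factors$G
  dplyr::mutate(tibble::as_tibble(spike),
                conc_reaction = .data$conc * isg_fraction *
                  factors$H / factors$I)
}
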