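#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an internal-standard curve
#'
#' @param x An `isg_curve` from [fit_internal_standard_curve()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @export
tidy.isg_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "dispersion"),
    estimate = c(x$intercept, x$dispersion),
    std.error = c(x$intercept_se, NA_real_)
  )
}

#' One-row summary of an internal-standard curve
#'
#' @inheritParams tidy.isg_curve
#' @return Tibble with intercept, dispersion, detection efficiency, Wald
#'   diagnostics and fit bookkeeping.
#' @export
glance.isg_curve <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept,
    intercept_se = x$intercept_se,
    dispersion = x$dispersion,
    detection_efficiency = exp(x$intercept),
    free_slope = x$free_slope,
    wald_p_free_slope = x$wald_p_free_slope,
    n_points = x$n_points,
    poisson_limit = x$poisson_limit,
    converged = x$converged,
    loglik = x$loglik
  )
}

#' Dose-response plot of an internal-standard curve
#'
#' Calibration points with the fitted fixed-slope line `log mu = x + b` on
#' natural-log axes.
#'
#' @param object An `isg_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isg_curve <- function(object, ...) {
  pts <- dplyr::filter(object$points, .data$reads > 0)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = log(.data$reads))) +
    ggplot2::geom_abline(intercept = object$intercept, slope = 1,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "ln(copies / uL reaction)",
      y = "ln(reads)",
      title = sprintf("Internal-standard curve: b = %.2f (DE %.1f reads/copy)",
                      object$intercept, exp(object$intercept))
    )
}

#' @rdname tidy.isg_curve
#' @export
tidy.isg_quant <- function(x, ...) x$table

#' One-row summary of an ASV quantification
#'
#' @param x An `isg_quant` from [quantify_asvs()].
#' @param ... Unused.
#' @return Tibble with ASV counts, LOQ and curve summary columns.
#' @export
glance.isg_quant <- function(x, ...) {
  bio <- dplyr::filter(x$table, .data$label == "biological")
  dplyr::bind_cols(
    tibble::tibble(
      n_biological = nrow(bio),
      n_above_loq = sum(bio$above_loq),
      loq_reads = as.numeric(x$loq),
      total_conc_dna = x$total_conc_dna
    ),
    glance(x$curve)[, c("intercept", "intercept_se", "dispersion",
                        "detection_efficiency", "wald_p_free_slope")]
  )
}

#' Quantified-abundance plot of an ASV table
#'
#' Per-ASV absolute concentrations with below-LOQ ASVs greyed out.
#'
#' @param object An `isg_quant`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isg_quant <- function(object, ...) {
  bio <- dplyr::filter(object$table, .data$label == "biological")
  ggplot2::ggplot(bio, ggplot2::aes(
    x = stats::reorder(.data$asv_id, -.data$conc_dna),
    y = .data$conc_dna, fill = .data$above_loq)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               name = "above LOQ") +
    ggplot2::labs(x = NULL, y = "copies / uL DNA") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
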