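nb_loglik <- function(b, theta, x, y) {
  sum(stats::dnbinom(y, size = theta, mu = exp(x + b), log = TRUE))
}

# Intercept MLE for fixed dispersion: the score in b is strictly decreasing,
# so the root is unique.
solve_intercept <- function(theta, x, y, b0) {
  score <- function(b) {
    mu <- exp(x + b)
    sum(y - (y + theta) * mu / (mu + theta))
  }
  stats::uniroot(score, lower = b0 - 30, upper = b0 + 30,
                 extendInt = "downX", tol = 1e-12)$root
}

#' Fit the internal-standard dose-response curve
#'
#' Negative-binomial regression of read counts on the natural-log template
#' concentration with the slope fixed at 1, so the linear predictor is
#' `log mu = x + b` and only the intercept `b` (log detection efficiency)
#' and the NB dispersion (size) are estimated. The fit alternates exact
#' intercept scoring given the dispersion with one-dimensional profile
#' maximization of the dispersion, then polishes both jointly; in the
#' no-overdispersion limit it reduces to the closed-form Poisson solution
#' `b = log(sum(y) / sum(exp(x)))`. A free-slope companion model is fitted
#' only to report the Wald p-value of the dose coefficient.
#'
#' @param data Data frame of calibration points with columns `x`
#'   (natural-log copies per uL reaction) and `reads` (non-negative counts).
#' @param theta_max Upper bound for the dispersion search; reaching it flags
#'   the Poisson limit.
#' @param max_iter,tol Outer alternation controls (log-likelihood change).
#' @return An object of class `isg_curve` with elements `intercept`,
#'   `dispersion`, `intercept_se`, `wald_p_free_slope`, `free_slope`,
#'   `n_points`, `converged`, `poisson_limit`, `loglik`, `iterations` and
#'   the point data. `exp(intercept)` is the detection efficiency in reads
#'   per copy.
#' @examples
#' pts <- tibble::tibble(x = log(c(40, 400, 4000, 40000)),
#'                       reads = round(exp(log(c(40, 400, 4000, 40000)) + 2)))
#' fit_internal_standard_curve(pts)$intercept
#' @export
fit_internal_standard_curve <- function(data, theta_max = 1e8,
                                        max_iter = 100, tol = 1e-10) {
  stopifnot(all(c("x", "reads") %in% names(data)))
  x <- as.numeric(data$x)
  y <- as.numeric(data$reads)
  if (length(y) < 2 || length(unique(x)) < 2) {
    stop("need at least 2 calibration points spanning 2 concentrations",
         call. = FALSE)
  }
  if (any(y < 0) || any(!is.finite(x))) {
    stop("reads must be non-negative and x finite", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("all calibration reads are zero; no curve can be fitted",
         call. = FALSE)
  }

  b0 <- log(sum(y) / sum(exp(x)))
  mu0 <- exp(x + b0)
  # moment initializer for the dispersion
  w <- sum((y - mu0)^2 - mu0) / sum(mu0^2)
  theta <- if (is.finite(w) && w > 1e-8) min(1 / w, theta_max) else theta_max

  b <- solve_intercept(theta, x, y, b0)
  ll <- nb_loglik(b, theta, x, y)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    opt <- stats::optimize(function(lt) nb_loglik(b, exp(lt), x, y),
                           lower = log(1e-4), upper = log(theta_max),
                           maximum = TRUE, tol = 1e-10)
    theta <- exp(opt$maximum)
    b <- solve_intercept(theta, x, y, b0)
    ll_new <- nb_loglik(b, theta, x, y)
    if (abs(ll_new - ll) < tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  # joint polish (guards against slow alternation on correlated surfaces)
  pol <- stats::optim(c(b, log(theta)),
                      function(p) -nb_loglik(p[1], exp(p[2]), x, y),
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  if (-pol$value >= ll) {
    b <- pol$par[1]
    theta <- min(exp(pol$par[2]), theta_max)
    ll <- nb_loglik(b, theta, x, y)
  }
  if (!converged && iter >= max_iter) {
    stop(sprintf(
      "NB calibration did not converge in %d iterations (last loglik %.6f)",
      max_iter, ll), call. = FALSE)
  }

  mu <- exp(x + b)
  se <- 1 / sqrt(sum(theta * mu / (mu + theta)))

  free <- tryCatch({
    fit <- suppressWarnings(MASS::glm.nb(reads ~ x, data = data))
    cf <- summary(fit)$coefficients
    list(slope = unname(cf["x", "Estimate"]), p = unname(cf["x", "Pr(>|z|)"]))
  }, error = function(e) {
    fit <- suppressWarnings(stats::glm(reads ~ x, family = stats::poisson(),
                                       data = data))
    cf <- summary(fit)$coefficients
    list(slope = unname(cf["x", "Estimate"]), p = unname(cf["x", "Pr(>|z|)"]))
  })

  structure(list(
    intercept = b,
    dispersion = theta,
    intercept_se = se,
    wald_p_free_slope = free$p,
    free_slope = free$slope,
    n_points = length(y),
    converged = TRUE,
    poisson_limit = theta >= theta_max * 0.99,
    loglik = ll,
    iterations = iter,
    points = tibble::tibble(x = x, reads = y)
  ), class = "isg_curve")
}

#' @export
print.isg_curve <- function(x, ...) {
  cat("Internal-standard curve (NB GLM, slope fixed at 1)\n")
  cat(sprintf("  intercept b: %.4f (SE %.4f)  detection efficiency: %.3f reads/copy\n",
              x$intercept, x$intercept_se, exp(x$intercept)))
  cat(sprintf("  dispersion (size): %s%s\n",
              format(x$dispersion, digits = 4),
              if (x$poisson_limit) " [Poisson limit]" else ""))
  cat(sprintf("  points: %d   free-slope Wald p: %.3g\n",
              x$n_points, x$wald_p_free_slope))
  invisible(x)
}

#' Convert read counts to in-reaction concentrations
#'
#' Inverts the fitted dose-response curve: `Z = reads / exp(b)`; zero reads
#' map to zero concentration.
#'
#' @param reads Non-negative read counts.
#' @param curve An [fit_internal_standard_curve()] object.
#' @return Copies per uL of reaction, strictly increasing in `reads`.
#' @export
reads_to_reaction_conc <- function(reads, curve) {
  stopifnot(inherits(curve, "isg_curve"), all(reads >= 0))
  ifelse(reads > 0, reads / exp(curve$intercept), 0)
}

#' Limit-of-quantification read threshold
#'
#' The read level of the lowest gradient level at which the internal
#' standards were detected: a level counts as detected only when every ISG
#' variant at that level has at least one read, and the threshold is the
#' mean read count across variants at the lowest such level. ASVs with reads
#' strictly below the threshold are below the LOQ.
#'
#' @param data Data frame of ISG observations with columns `level`
#'   (gradient concentration) and `reads`.
#' @return The threshold read count, with the defining gradient level as
#'   attribute `level`.
#' @export
loq_threshold <- function(data) {
  stopifnot(all(c("level", "reads") %in% names(data)))
  lev <- dplyr::summarise(dplyr::group_by(data, .data$level),
                          detected = all(.data$reads > 0),
                          mean_reads = mean(.data$reads), .groups = "drop")
  det <- dplyr::filter(lev, .data$detected)
  if (nrow(det) == 0) {
    stop("no internal-standard level fully detected; quantification impossible",
         call. = FALSE)
  }
  lo <- dplyr::slice_min(det, .data$level, n = 1)
  structure(lo$mean_reads, level = lo$level)
}

#' Absolute quantification of an ASV table against spiked standards
#'
#' Builds calibration points from the internal-standard rows (dose = log
#' expected in-reaction concentration of each variant/level), fits the
#' fixed-slope NB curve, converts every biological ASV's reads through the
#' curve and the volume chain to copies per uL reaction, per uL DNA and per
#' unit sample, and attaches limit-of-quantification flags.
#'
#' @param asv_table Data frame with columns `asv_id`, `reads`, `label`
#'   (`"ISG"` or `"biological"`); ISG rows must carry `variant_id` and
#'   `level` matching the spike design.
#' @param spike A [spikein_series()] describing the added standards.
#' @param factors A [conversion_factors()] object.
#' @param sample A [sample_factors()] object.
#' @param extraction_efficiency Assumed DNA extraction efficiency.
#' @return Object of class `isg_quant`: list with `table` (the quantified
#'   ASV table), `curve`, `loq`, and `total_conc_dna` (summed biological
#'   concentration, copies/uL DNA).
#' @export
quantify_asvs <- function(asv_table, spike = default_spikein_gradient(),
                          factors = conversion_factors(),
                          sample = sample_factors(),
                          extraction_efficiency = 1) {
  req <- c("asv_id", "reads", "label")
  if (!all(req %in% names(asv_table))) {
    stop("asv_table must have columns asv_id, reads, label", call. = FALSE)
  }
  if (anyDuplicated(asv_table$asv_id)) {
    stop("duplicate asv_id in input table", call. = FALSE)
  }
  isg <- dplyr::filter(asv_table, .data$label == "ISG")
  if (nrow(isg) == 0) stop("no internal-standard rows in table", call. = FALSE)
  doses <- isg_reaction_conc(spike, factors)
  isg <- dplyr::inner_join(isg, doses, by = c("variant_id", "level"))
  if (nrow(isg) == 0) {
    stop("ISG rows do not match the spike design (variant_id/level)",
         call. = FALSE)
  }
  pts <- isg |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::transmute(x = log(.data$conc_reaction), reads = .data$reads,
                     variant_id = .data$variant_id)
  if (nrow(pts) < 2 || length(unique(pts$x)) < 2) {
    stop("fewer than 2 detected internal-standard levels", call. = FALSE)
  }
  curve <- fit_internal_standard_curve(pts)
  loq <- loq_threshold(isg)

  out <- asv_table |>
    tibble::as_tibble() |>
    dplyr::mutate(
      conc_reaction = reads_to_reaction_conc(.data$reads, curve),
      conc_dna = reaction_to_dna_conc(.data$conc_reaction, factors,
                                      include_sample_mix = TRUE),
      conc_sample = dna_to_sample_conc(.data$conc_dna, sample,
                                       extraction_efficiency),
      above_loq = .data$reads >= as.numeric(loq)
    )
  bio <- dplyr::filter(out, .data$label == "biological")
  structure(list(
    table = out,
    curve = curve,
    loq = loq,
    total_conc_dna = sum(bio$conc_dna)
  ), class = "isg_quant")
}

#' @export
print.isg_quant <- function(x, ...) {
  bio <- dplyr::filter(x$table, .data$label == "biological")
  cat(sprintf(
    "ASV quantification: %d biological ASVs (%d above LOQ of %.1f reads)\n",
    nrow(bio), sum(bio$above_loq), as.numeric(x$loq)))
  cat(sprintf("  total biological concentration: %.4g copies/uL DNA\n",
              x$total_conc_dna))
  print(x$curve)
  invisible(x)
}
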