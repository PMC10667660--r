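test_that("mass-to-copies conversion matches direct arithmetic", {
  expect_equal(mass_to_copies(0, 615), 0)
  expect_equal(mass_to_copies(1, 615), 6.02e23 / (660 * 1e9 * 615))
  expect_equal(mass_to_copies(1, 615) / mass_to_copies(1, 1230), 2)
  expect_equal(mass_to_copies(3, 100), 3 * mass_to_copies(1, 100))
  expect_error(mass_to_copies(1, 0), "dna_length")
})

test_that("equal-volume gradient mixing reproduces the standard total", {
  s <- build_spikein_series(4.0e8, c(100, 1e3, 1e4, 1e5))
  expect_equal(attr(s, "total_conc"), 1.111e6)
  expect_equal(s$level, c(4e6, 4e5, 4e4, 4e3))
  expect_equal(s$conc, s$level / 4)

  one <- build_spikein_series(5e5, 1)
  expect_equal(attr(one, "total_conc"), 5e5)

  two <- build_spikein_series(1e6, c(2, 2))
  expect_equal(two$conc, c(2.5e5, 2.5e5))
  expect_equal(attr(two, "total_conc"), 5e5)
  expect_error(build_spikein_series(1e6, numeric(0)), "empty")
})

test_that("the volume chain is multiplicative and invertible", {
  id <- conversion_factors(1, 1, 1, 1, 1, 1)
  expect_equal(expected_reaction_conc(123, id), 123)

  f <- conversion_factors(D = 1, E = 10, F = 3, G = 4, H = 2.5, I = 50)
  expect_equal(expected_reaction_conc(1e6, f), 3750)
  expect_equal(reaction_to_dna_conc(3750, f), 1e6)
  for (conc in c(1, 17.3, 2.4e8)) {
    expect_equal(reaction_to_dna_conc(expected_reaction_conc(conc, f), f),
                 conc, tolerance = 1e-12)
  }
  # qPCR variant omits the sample+ISG mixing term
  expect_equal(expected_reaction_conc(1e6, f, include_sample_mix = FALSE),
               5000)
  expect_error(conversion_factors(D = 2, E = 1), "D <= E")
})

test_that("sample-level reporting follows X = Y * C / A", {
  s <- sample_factors(extraction_vol = 100, sample_amount = 0.2, unit = "g")
  expect_equal(dna_to_sample_conc(1e6, s), 5e8)
  expect_equal(dna_to_sample_conc(7, sample_factors(50, 50)), 7)
  expect_equal(dna_to_sample_conc(1e6, sample_factors(100, 0.1)),
               2 * dna_to_sample_conc(1e6, s))
  expect_error(sample_factors(100, 0), "sample_amount")
})

test_that("noiseless exponential data recover the intercept", {
  x <- log(c(40, 400, 4000, 40000))
  pts <- tibble::tibble(x = x, reads = round(exp(x + 2)))
  fit <- fit_internal_standard_curve(pts)
  expect_true(abs(fit$intercept - 2) < 0.02)
  expect_true(fit$converged)
})

test_that("the fixed-slope fit attains the Poisson closed form without overdispersion", {
  x <- log(c(40, 400, 4000, 40000))
  # at the dispersion cap the intercept equals ln(sum y / sum e^x) exactly
  for (seed in 1:5) {
    y <- withr::with_seed(seed, stats::rpois(4, exp(x + 1.5)))
    b_pois <- log(sum(y) / sum(exp(x)))
    b_cap <- isgquant:::solve_intercept(1e10, x, y, b_pois)
    expect_true(abs(b_cap - b_pois) < 1e-6)
  }
  # and fits on progressively less overdispersed data approach it
  err_for_size <- function(size) {
    y <- withr::with_seed(99, stats::rnbinom(4, mu = exp(x + 1.5),
                                             size = size))
    fit <- fit_internal_standard_curve(tibble::tibble(x = x, reads = y))
    abs(fit$intercept - log(sum(y) / sum(exp(x))))
  }
  errs <- vapply(c(5, 5e3, 5e7), err_for_size, numeric(1))
  expect_lt(errs[3], 1e-6)
  expect_lt(errs[3], errs[1])
})

test_that("the NB fit beats a dense likelihood grid on random small instances", {
  for (seed in 1:12) {
    dat <- withr::with_seed(seed, {
      n <- sample(4:8, 1)
      x <- log(stats::runif(n, 5, 5000))
      b <- stats::runif(1, -1, 3)
      th <- stats::runif(1, 0.5, 10)
      tibble::tibble(x = x, reads = stats::rnbinom(n, mu = exp(x + b),
                                                   size = th))
    })
    if (all(dat$reads == 0) || length(unique(dat$x)) < 2) next
    fit <- fit_internal_standard_curve(dat)
    grid <- expand.grid(b = seq(fit$intercept - 1, fit$intercept + 1,
                                length.out = 81),
                        lt = seq(log(0.05), log(500), length.out = 81))
    ll_grid <- max(mapply(function(b, lt) {
      sum(stats::dnbinom(dat$reads, size = exp(lt), mu = exp(dat$x + b),
                         log = TRUE))
    }, grid$b, grid$lt))
    expect_gte(fit$loglik, ll_grid - 1e-6)
  }
})

test_that("intercept inversion converts reads to concentrations", {
  x <- log(c(10, 100, 1000))
  fit <- fit_internal_standard_curve(
    tibble::tibble(x = x, reads = round(exp(x + log(10)))))
  expect_equal(reads_to_reaction_conc(exp(fit$intercept), fit), 1)
  expect_equal(reads_to_reaction_conc(0, fit), 0)
  expect_equal(reads_to_reaction_conc(250, fit), 250 / exp(fit$intercept))
  r <- 0:50
  expect_true(all(diff(reads_to_reaction_conc(r, fit)) >= 0))
  # reads = 10 * copies exactly, so b = ln 10 and 250 reads -> 25 copies
  expect_equal(reads_to_reaction_conc(250, fit), 25, tolerance = 1e-3)
})

test_that("detection efficiency is reads per copy and links to the intercept", {
  expect_equal(detection_efficiency(90, 10), 9)
  expect_equal(detection_efficiency(0, 5), 0)
  expect_error(detection_efficiency(10, 0), "copies")

  x <- log(c(20, 200, 2000, 20000))
  fit <- fit_internal_standard_curve(
    tibble::tibble(x = x, reads = round(exp(x + 1.2))))
  de <- detection_efficiency(round(exp(x + 1.2)), exp(x))
  expect_true(all(abs(de - exp(fit$intercept)) / exp(fit$intercept) < 0.02))
})

test_that("degenerate calibration inputs raise errors", {
  expect_error(fit_internal_standard_curve(
    tibble::tibble(x = log(c(10, 100)), reads = c(0, 0))), "zero")
  expect_error(fit_internal_standard_curve(
    tibble::tibble(x = c(1, 1), reads = c(5, 7))), "2 concentrations")
})

test_that("the LOQ is the read level of the lowest fully detected standard", {
  d <- tibble::tibble(level = c(1e3, 1e4, 1e5, 1e6),
                      reads = c(0, 35, 300, 2900))
  thr <- loq_threshold(d)
  expect_equal(as.numeric(thr), 35)
  expect_equal(attr(thr, "level"), 1e4)

  all_det <- tibble::tibble(level = c(1e3, 1e4), reads = c(4, 50))
  expect_equal(as.numeric(loq_threshold(all_det)), 4)

  # variant-resolved: a level with any undetected variant does not count
  vr <- tibble::tibble(level = rep(c(1e3, 1e4), each = 2),
                       reads = c(3, 0, 40, 44))
  expect_equal(as.numeric(loq_threshold(vr)), 42)

  expect_error(loq_threshold(tibble::tibble(level = 1e3, reads = 0)),
               "impossible")
})

test_that("quantify_asvs flags ASVs below the LOQ but still reports them", {
  spike <- default_spikein_gradient()
  doses <- isg_reaction_conc(spike)
  tab <- dplyr::bind_rows(
    tibble::tibble(asv_id = spike$variant_id, reads = round(
      5 * doses$conc_reaction), label = "ISG",
      variant_id = spike$variant_id, level = spike$level),
    tibble::tibble(asv_id = c("bioA", "bioB"), reads = c(10, 5000),
                   label = "biological", variant_id = NA, level = NA)
  )
  q <- quantify_asvs(tab, spike)
  bio <- dplyr::filter(q$table, label == "biological")
  expect_equal(bio$above_loq, c(FALSE, TRUE))
  expect_true(all(bio$conc_dna > 0))
  expect_equal(bio$conc_reaction, bio$reads / exp(q$curve$intercept))
})

test_that("an ISG-only library yields an empty biological table and a valid curve", {
  spike <- default_spikein_gradient()
  doses <- isg_reaction_conc(spike)
  tab <- tibble::tibble(asv_id = spike$variant_id,
                        reads = round(8 * doses$conc_reaction),
                        label = "ISG", variant_id = spike$variant_id,
                        level = spike$level)
  q <- quantify_asvs(tab, spike)
  expect_equal(nrow(dplyr::filter(q$table, label == "biological")), 0)
  expect_equal(q$total_conc_dna, 0)
  expect_true(abs(q$curve$intercept - log(8)) < 0.05)
})

test_that("quantification is invariant under row reordering", {
  cfg <- simulation_config()
  sim <- simulate_library(cfg, seed = 9)
  q1 <- quantify_asvs(sim$asv_table, cfg$spike, cfg$factors, cfg$sample)
  shuffled <- withr::with_seed(1, sim$asv_table[sample(nrow(sim$asv_table)), ])
  q2 <- quantify_asvs(shuffled, cfg$spike, cfg$factors, cfg$sample)
  expect_equal(q1$curve$intercept, q2$curve$intercept)
  expect_equal(q1$total_conc_dna, q2$total_conc_dna)
  t1 <- dplyr::arrange(q1$table, asv_id)
  t2 <- dplyr::arrange(q2$table, asv_id)
  expect_equal(t1$conc_dna, t2$conc_dna)
})

test_that("tidy, glance and autoplot methods expose the fit", {
  x <- log(c(10, 100, 1000))
  fit <- fit_internal_standard_curve(
    tibble::tibble(x = x, reads = round(exp(x + 1))))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "dispersion"))
  gl <- glance(fit)
  expect_equal(gl$detection_efficiency, exp(fit$intercept))
  expect_s3_class(autoplot(fit), "ggplot")
})
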