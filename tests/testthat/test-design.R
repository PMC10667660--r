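test_that("the full-panel layout satisfies every constraint", {
  ps <- isg_primer_sets()
  cons <- design_constraints()
  layout <- build_layout(ps, cons)
  expect_true(check_layout(layout, ps, cons$total_length, cons$min_gap))
  # 805R is one shared site
  expect_equal(sum(layout$site == "16S_805R"), 1)
  expect_equal(nrow(layout), 8)
})

test_that("a fully forced one-pair layout is placed by length arithmetic", {
  ps <- primer_set("toy", strrep("A", 18), strrep("T", 17), "F", "R", "x", 100)
  layout <- build_layout(ps, design_constraints(total_length = 100,
                                                n_variants = 1))
  f <- layout[layout$orientation == "forward", ]
  r <- layout[layout$orientation == "reverse", ]
  expect_equal(c(f$start, f$end), c(1, 18))
  expect_equal(c(r$start, r$end), c(84, 100))
})

test_that("randomized feasible instances solve and verify", {
  for (seed in 1:12) {
    inst <- random_feasible_panel(seed)
    cons <- design_constraints(total_length = inst$total)
    layout <- build_layout(inst$primers, cons)
    expect_true(check_layout(layout, inst$primers, inst$total, cons$min_gap),
                info = paste("seed", seed))
  }
})

test_that("layout solving is deterministic", {
  ps <- isg_primer_sets()
  expect_identical(build_layout(ps), build_layout(ps))
})

test_that("infeasible instances raise an explicit error", {
  ps <- rbind(
    primer_set("p1", strrep("A", 18), strrep("T", 17), "F1", "R1", "x", 100),
    primer_set("p2", strrep("C", 18), strrep("G", 17), "F2", "R2", "x", 100)
  )
  expect_error(build_layout(ps, design_constraints(total_length = 100)),
               "infeasible")
  expect_error(build_layout(ps[1, ], design_constraints(total_length = 50)),
               "infeasible")
})

test_that("spacer generation is seeded, GC-balanced and variant-distinct", {
  ps <- isg_primer_sets()
  cons <- design_constraints()
  d1 <- design_isgs(ps, cons, seed = 11)
  d2 <- design_isgs(ps, cons, seed = 11)
  expect_identical(d1$sequence, d2$sequence)
  d3 <- design_isgs(ps, cons, seed = 12)
  expect_false(any(d3$sequence %in% d1$sequence))

  expect_equal(nrow(d1), 4)
  expect_equal(unique(d1$total_length), cons$total_length)
  expect_true(all(abs(d1$gc_fraction - cons$gc_target) <= cons$gc_tolerance))
  # variants agree at primer sites and differ elsewhere
  lay <- isg_layout(d1)
  for (i in seq_len(nrow(lay))) {
    site_seq <- unique(substring(d1$sequence, lay$start[i], lay$end[i]))
    expect_length(site_seq, 1)
    expect_identical(site_seq, lay$concrete[i])
  }
  expect_equal(length(unique(d1$sequence)), 4)
})

test_that("an all-spacer molecule hits the GC target", {
  empty_layout <- build_layout(
    primer_set("toy", "ACGTACGT", "ACGTACGT", "F", "R", "x", 100),
    design_constraints(total_length = 200)
  )[0, ]
  cons <- design_constraints(total_length = 10, gc_target = 0.5,
                             gc_tolerance = 0.1, n_variants = 1)
  d <- generate_spacers(empty_layout, cons, isg_primer_sets()[0, ], seed = 3)
  gc_count <- nchar(gsub("[AT]", "", d$sequence))
  expect_true(gc_count >= 4 && gc_count <= 6)
})

test_that("cross-match screening flags planted primers and honours the whitelist", {
  ps <- isg_primer_sets()[4, ]  # 341F/805R
  planted <- concretize_primer(ps$forward)
  seqn <- paste0(strrep("A", 30), planted, strrep("T", 30))
  hits <- screen_primer_matches(seqn, ps, allowed_sites = NULL,
                                max_mismatch = 0)
  expect_true(nrow(hits) >= 1)
  expect_true(any(hits$start == 31 & hits$strand == "+"))

  allowed <- tibble::tibble(start = 31, end = 30 + nchar(planted))
  expect_equal(nrow(screen_primer_matches(seqn, ps, allowed, 0)), 0)

  # two mismatches planted at non-degenerate primer positions (341F is
  # degenerate at 9 and 13): caught at tolerance 2, missed at tolerance 1
  mm <- planted
  substr(mm, 2, 2) <- "A"
  substr(mm, 6, 6) <- "T"
  seq2 <- paste0(strrep("T", 20), mm, strrep("A", 20))
  h2 <- screen_primer_matches(seq2, ps, NULL, 2)
  expect_true(any(h2$start == 21 & h2$mismatches == 2))
  h1 <- screen_primer_matches(seq2, ps, NULL, 1)
  expect_false(any(h1$start == 21 & h1$strand == "+"))
})

test_that("IUPAC scanning agrees with brute-force primer expansion", {
  primers <- c("CCTACGGGNGGCWGCAG", "GAASGCNGAGAAGAASGC", "ACGTRYSW")
  set.seed(404)
  for (p in primers) {
    for (rep in 1:4) {
      tpl <- random_concrete_seq(sample(60:200, 1))
      for (tol in 0:2) {
        got <- isgquant:::scan_one_strand(p, tpl, tol, "+")
        got <- rbind(got, isgquant:::scan_one_strand(p, tpl, tol, "-"))
        want <- oracle_scan(p, tpl, tol)
        got <- got[order(got$strand, got$start), ]
        expect_equal(nrow(got), nrow(want))
        if (nrow(got) > 0) {
          expect_equal(got$start, want$start)
          expect_equal(got$mismatches, want$mismatches)
        }
      }
    }
  }
})

test_that("designed ISGs are self-consistent under in-silico PCR and screening", {
  d <- design_isgs(seed = 7)
  ps <- isg_primer_sets()
  lay <- isg_layout(d)
  for (v in seq_len(nrow(d))) {
    for (i in seq_len(nrow(ps))) {
      prods <- insilico_pcr(d$sequence[v], ps$forward[i], ps$reverse[i])
      expect_equal(nrow(prods), 1)
      expect_equal(prods$length, ps$expected_amplicon_len[i])
    }
    expect_equal(nrow(screen_primer_matches(d$sequence[v], ps, lay, 2)), 0)
  }
})

test_that("in-silico PCR handles toy and negative templates", {
  f <- "GGNGACTGGGACTTCTGG"
  r <- "ACGTCCTTACCGAAGGT"
  tpl <- paste0(concretize_primer(f), "CCCCC", revcomp(concretize_primer(r)))
  prods <- insilico_pcr(tpl, f, r)
  expect_equal(nrow(prods), 1)
  expect_equal(prods$start, 1L)
  expect_equal(prods$end, 40L)
  expect_equal(prods$length, 40L)
  expect_identical(prods$sequence, tpl)

  none <- insilico_pcr(strrep("AT", 40), f, r)
  expect_equal(nrow(none), 0)
  expect_error(insilico_pcr("ACGT", f, r), "shorter")
})
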