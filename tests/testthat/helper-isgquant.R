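# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning/solver code paths.

# IUPAC classes written out by hand (not via iupac_codes()).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Expand a degenerate primer into every concrete realization.
expand_primer <- function(primer) {
  sets <- ORACLE_IUPAC[strsplit(primer, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force sliding-window scan: hit where the minimum Hamming distance
# over all concrete realizations is <= tol. Plus-strand coordinates.
oracle_scan <- function(primer, template, tol) {
  reals <- expand_primer(primer)
  k <- nchar(primer)
  L <- nchar(template)
  hits <- list()
  scan_strand <- function(subj, strand) {
    res <- list()
    if (k > nchar(subj)) return(res)
    for (s in 1:(nchar(subj) - k + 1)) {
      win <- substr(subj, s, s + k - 1)
      d <- min(vapply(reals, function(r) {
        sum(strsplit(r, "")[[1]] != strsplit(win, "")[[1]])
      }, numeric(1)))
      if (d <= tol) {
        st <- if (strand == "+") s else L - (s + k - 1) + 1
        res[[length(res) + 1]] <- data.frame(start = st, end = st + k - 1,
                                             strand = strand, mismatches = d)
      }
    }
    res
  }
  out <- c(scan_strand(template, "+"),
           scan_strand(oracle_revcomp(template), "-"))
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$strand, df$start), , drop = FALSE]
}

# Independent verifier of layout constraints: amplicon spans, bounds, gaps.
check_layout <- function(layout, primers, total_length, min_gap = 1) {
  ok <- TRUE
  msgs <- character(0)
  for (i in seq_len(nrow(primers))) {
    f <- layout[layout$site == primers$forward_name[i] &
                  layout$orientation == "forward", ]
    r <- layout[layout$site == primers$reverse_name[i] &
                  layout$orientation == "reverse", ]
    span <- r$end - f$start + 1
    if (span != primers$expected_amplicon_len[i]) {
      ok <- FALSE
      msgs <- c(msgs, sprintf("%s span %d != %d", primers$name[i], span,
                              primers$expected_amplicon_len[i]))
    }
  }
  if (any(layout$start < 1) || any(layout$end > total_length)) {
    ok <- FALSE
    msgs <- c(msgs, "site out of bounds")
  }
  lay <- layout[order(layout$start), ]
  if (nrow(lay) > 1) {
    gaps <- lay$start[-1] - lay$end[-nrow(lay)] - 1
    if (any(gaps < min_gap)) {
      ok <- FALSE
      msgs <- c(msgs, "gap constraint violated")
    }
  }
  if (!ok) attr(ok, "msgs") <- msgs
  ok
}

# Random layout instance that is feasible by construction: disjoint pair
# regions laid end to end.
random_feasible_panel <- function(seed) {
  set.seed(seed)
  n_pairs <- sample(2:3, 1)
  rows <- list()
  offset <- 0
  for (i in seq_len(n_pairs)) {
    lf <- sample(8:20, 1)
    lr <- sample(8:20, 1)
    amp <- lf + lr + sample(2:40, 1)
    rows[[i]] <- isgquant::primer_set(
      paste0("pair", i),
      paste(sample(c("A", "C", "G", "T"), lf, replace = TRUE), collapse = ""),
      paste(sample(c("A", "C", "G", "T"), lr, replace = TRUE), collapse = ""),
      paste0("F", i), paste0("R", i), "synthetic", amp)
    offset <- offset + amp + 2
  }
  list(primers = do.call(rbind, rows), total = offset + 5)
}

random_concrete_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
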