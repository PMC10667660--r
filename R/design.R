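#' Design constraints for internal-standard genes
#'
#' @param total_length Synthesis length of each ISG in bp (default 615).
#' @param gc_target Target overall GC fraction (default 0.5).
#' @param gc_tolerance Allowed deviation from `gc_target` (default 0.05).
#' @param min_gap Minimum number of intervening bases between primer sites
#'   (default 1, so that no two sites are adjacent).
#' @param n_variants Number of spacer variants to emit (default 4).
#' @param mismatch_tolerance Mismatch allowance for cross-match screening
#'   (default 2).
#' @param max_retries Spacer redraws allowed before giving up (default 25).
#' @return A list of class `isg_constraints`.
#' @export
design_constraints <- function(total_length = 615, gc_target = 0.5,
                               gc_tolerance = 0.05, min_gap = 1,
                               n_variants = 4, mismatch_tolerance = 2,
                               max_retries = 25) {
  stopifnot(total_length >= 1, gc_target > 0, gc_target < 1,
            gc_tolerance >= 0, min_gap >= 0, n_variants >= 1,
            mismatch_tolerance >= 0, max_retries >= 1)
  structure(list(total_length = as.integer(total_length),
                 gc_target = gc_target, gc_tolerance = gc_tolerance,
                 min_gap = as.integer(min_gap),
                 n_variants = as.integer(n_variants),
                 mismatch_tolerance = as.integer(mismatch_tolerance),
                 max_retries = as.integer(max_retries)),
            class = "isg_constraints")
}

# Distinct physical sites of a primer panel. Primers shared between pairs
# (by name) collapse to a single site.
panel_sites <- function(primers) {
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(site = primers$forward_name, orientation = "forward",
                   seq = primers$forward),
    tibble::tibble(site = primers$reverse_name, orientation = "reverse",
                   seq = primers$reverse)
  )) |>
    dplyr::mutate(len = nchar(.data$seq))
}

#' Place primer sites on the ISG backbone
#'
#' Solves for 1-based inclusive coordinates of every distinct primer site so
#' that, for each primer pair, the span from the start of its forward site to
#' the end of its reverse site equals the expected amplicon length, all sites
#' fall inside the molecule, and any two sites are separated by at least
#' `min_gap` intervening bases. Sites linked by a shared primer form rigid
#' blocks; blocks are placed by an exhaustive smallest-coordinate search with
#' backtracking, so the result is deterministic and left-packed.
#'
#' @param primers Primer-set tibble (see [primer_set()]).
#' @param constraints An [design_constraints()] object.
#' @return Layout tibble: `site`, `orientation`, `start`, `end`, `length`,
#'   `seq` (IUPAC, primer orientation) and `concrete` (bases as they appear
#'   on the ISG plus strand).
#' @export
build_layout <- function(primers, constraints = design_constraints()) {
  total <- constraints$total_length
  gap <- constraints$min_gap
  if (max(primers$expected_amplicon_len) > total) {
    stop(sprintf(
      "infeasible layout: amplicon length %d exceeds total length %d",
      max(primers$expected_amplicon_len), total), call. = FALSE)
  }
  sites <- panel_sites(primers)
  n <- nrow(sites)
  idx <- stats::setNames(seq_len(n), paste(sites$site, sites$orientation))

  # relative-offset graph: start(reverse) - start(forward) is fixed per pair
  comp <- seq_len(n)          # component id per site
  off <- rep(0L, n)           # start offset relative to component anchor
  for (i in seq_len(nrow(primers))) {
    f <- idx[[paste(primers$forward_name[i], "forward")]]
    r <- idx[[paste(primers$reverse_name[i], "reverse")]]
    delta <- primers$expected_amplicon_len[i] - sites$len[r]  # start r - start f
    if (comp[f] == comp[r]) {
      if (off[r] - off[f] != delta) {
        stop(sprintf(
          "infeasible layout: pair '%s' conflicts with a shared-primer constraint",
          primers$name[i]), call. = FALSE)
      }
    } else {
      shift <- off[f] + delta - off[r]
      members <- comp == comp[r]
      off[members] <- off[members] + shift
      comp[members] <- comp[f]
    }
  }

  comp_ids <- unique(comp)
  blocks <- lapply(comp_ids, function(cid) {
    m <- which(comp == cid)
    o <- off[m] - min(off[m])     # normalize anchor to 0
    list(members = m, off = o, len = sites$len[m],
         span = max(o + sites$len[m]))
  })
  # intra-block overlap check (fixed geometry, no placement can fix it)
  for (b in blocks) {
    k <- order(b$off)
    s <- b$off[k]; e <- b$off[k] + b$len[k] - 1
    if (length(s) > 1 && any(s[-1] - e[-length(e)] - 1 < gap)) {
      j <- which(s[-1] - e[-length(e)] - 1 < gap)[1]
      stop(sprintf(
        "infeasible layout: sites '%s' and '%s' are forced closer than min_gap",
        sites$site[b$members[k[j]]], sites$site[b$members[k[j + 1]]]),
        call. = FALSE)
    }
  }

  placed_s <- integer(0); placed_e <- integer(0)
  bases <- integer(length(blocks))
  node_budget <- 5e6

  solve <- function(bi) {
    if (bi > length(blocks)) return(TRUE)
    b <- blocks[[bi]]
    for (base in 1:(total - b$span + 1)) {
      node_budget <<- node_budget - 1
      if (node_budget < 0) {
        stop("infeasible layout: search limit reached without a placement",
             call. = FALSE)
      }
      s <- base + b$off; e <- s + b$len - 1
      ok <- TRUE
      for (j in seq_along(placed_s)) {
        if (!all(s > placed_e[j] + gap | e < placed_s[j] - gap)) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        old_n <- length(placed_s)
        placed_s <<- c(placed_s, s); placed_e <<- c(placed_e, e)
        bases[bi] <<- base
        if (solve(bi + 1)) return(TRUE)
        placed_s <<- placed_s[seq_len(old_n)]
        placed_e <<- placed_e[seq_len(old_n)]
      }
    }
    FALSE
  }
  if (total < max(vapply(blocks, function(b) b$span, numeric(1))) ||
      !solve(1)) {
    stop(sprintf(
      paste0("infeasible layout: no placement of %d primer-site blocks in ",
             "%d bp satisfies the amplicon-length and min_gap (%d) ",
             "constraints"), length(blocks), total, gap), call. = FALSE)
  }

  start <- integer(n)
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    start[b$members] <- bases[bi] + b$off
  }
  layout <- sites |>
    dplyr::mutate(
      start = as.integer(start),
      end = as.integer(start + .data$len - 1L),
      length = as.integer(.data$len),
      concrete = ifelse(.data$orientation == "forward",
                        vapply(.data$seq, concretize_primer, character(1)),
                        vapply(.data$seq, function(s)
                          revcomp(concretize_primer(s)), character(1)))
    ) |>
    dplyr::select("site", "orientation", "start", "end", "length",
                  "seq", "concrete") |>
    dplyr::arrange(.data$start)
  layout
}

# One spacer fill: random gap bases with the G/C count chosen to land the
# whole molecule on the GC target.
fill_spacers_once <- function(skeleton, gap_idx, gc_fixed, constraints) {
  total <- constraints$total_length
  n_gc <- round(constraints$gc_target * total) - gc_fixed
  n_gc <- max(0L, min(length(gap_idx), n_gc))
  gc_pos <- sample(gap_idx, n_gc)
  skeleton[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  at_pos <- setdiff(gap_idx, gc_pos)
  skeleton[at_pos] <- sample(c("A", "T"), length(at_pos), replace = TRUE)
  paste(skeleton, collapse = "")
}

#' Fill spacers to produce ISG sequence variants
#'
#' Spacer regions between the laid-out primer sites are filled with seeded
#' random bases whose G/C count brings each whole molecule onto the GC
#' target; every candidate is screened against unintended primer matches
#' (both strands, `mismatch_tolerance` mismatches) and redrawn on failure.
#' All variants share the primer-site bases and differ only in the spacers.
#'
#' @param layout Layout tibble from [build_layout()].
#' @param constraints An [design_constraints()] object.
#' @param primers Primer-set tibble used for cross-match screening.
#' @param seed Integer seed; the whole set is reproducible from it.
#' @return Tibble with one row per variant: `variant_id`, `sequence`,
#'   `total_length`, `gc_fraction`, `seed`.
#' @export
generate_spacers <- function(layout, constraints, primers, seed = 1) {
  total <- constraints$total_length
  if (nrow(layout) > 0 && max(layout$end) > total) {
    stop("layout exceeds total_length", call. = FALSE)
  }
  skeleton <- rep(NA_character_, total)
  for (i in seq_len(nrow(layout))) {
    skeleton[layout$start[i]:layout$end[i]] <-
      strsplit(layout$concrete[i], "")[[1]]
  }
  gap_idx <- which(is.na(skeleton))
  gc_fixed <- if (all(is.na(skeleton))) 0L else
    sum(skeleton %in% c("G", "C"), na.rm = TRUE)

  withr::with_seed(seed, {
    seqs <- character(0)
    for (v in seq_len(constraints$n_variants)) {
      ok <- FALSE
      for (try in seq_len(constraints$max_retries)) {
        cand <- fill_spacers_once(skeleton, gap_idx, gc_fixed, constraints)
        gc <- gc_content(cand)
        if (abs(gc - constraints$gc_target) > constraints$gc_tolerance) next
        if (cand %in% seqs) next
        viol <- screen_primer_matches(cand, primers, layout,
                                      constraints$mismatch_tolerance)
        if (nrow(viol) == 0) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf(
          "could not satisfy GC/screening constraints for variant %d after %d retries",
          v, constraints$max_retries), call. = FALSE)
      }
      seqs <- c(seqs, cand)
    }
    tibble::tibble(
      variant_id = sprintf("ISG%02d", seq_along(seqs)),
      sequence = seqs,
      total_length = nchar(seqs),
      gc_fraction = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE),
      seed = as.integer(seed)
    )
  })
}

#' Design a set of internal-standard gene variants
#'
#' One-call designer: solves the primer-site layout for the panel, then fills
#' GC-balanced, cross-match-screened spacer variants. The returned tibble
#' carries the layout and constraints as attributes (`isg_layout()`,
#' `attr(x, "constraints")`).
#'
#' @inheritParams generate_spacers
#' @param primers Primer-set tibble (default [isg_primer_sets()]).
#' @return The variants tibble from [generate_spacers()], with attributes
#'   `layout` and `constraints`.
#' @examples
#' \donttest{
#' designs <- design_isgs(seed = 1)
#' isg_layout(designs)
#' }
#' @export
design_isgs <- function(primers = isg_primer_sets(),
                        constraints = design_constraints(), seed = 1) {
  layout <- build_layout(primers, constraints)
  designs <- generate_spacers(layout, constraints, primers, seed)
  attr(designs, "layout") <- layout
  attr(designs, "constraints") <- constraints
  class(designs) <- c("isg_design_set", class(designs))
  designs
}

#' @rdname design_isgs
#' @param x A design set returned by [design_isgs()].
#' @export
isg_layout <- function(x) attr(x, "layout")
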