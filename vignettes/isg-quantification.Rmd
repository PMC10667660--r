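---
title: "Spike-in calibration of amplicon sequencing with synthetic internal standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibration of amplicon sequencing with synthetic internal standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isgquant)
```

## The method

Amplicon sequencing is, in effect, quantitative competitive PCR: templates
compete for the same primers and reagents, so read counts are proportional
to template amounts only within a library and only up to a library-specific
efficiency. Adding synthetic internal-standard genes (ISGs) at known copy
numbers turns that proportionality into a calibration. An ISG is a single
synthetic molecule carrying the binding sites of several primer sets —
here two *pmoA* pairs (189f/650r, 189f/682r), the *amoA* 1F/2R pair, and
the 16S rRNA 341F/805R and 515F/805R pairs, with 805R and 189f shared
between pairs — so one spike-in calibrates every marker at once.

### Dose–response model

For each library the ISG read counts are regressed on their known
in-reaction doses with a negative-binomial GLM whose slope is fixed at 1:

$$\ln \mu_i = x_i + b,\qquad y_i \sim \mathrm{NB}(\mu_i, \theta),$$

where $x_i = \ln(\text{copies}\,\mu\mathrm{L}^{-1}\ \text{reaction})$ and
$y_i$ is the read count. Fixing the slope encodes the competitive-PCR
assumption that reads are *proportional* to template amount; the intercept
$b$ absorbs the library's overall yield, and $e^b$ is the detection
efficiency in reads per copy. Unknown counts convert back through
$Z = y / e^b$ and then up the volume chain (below). Zero reads map to zero
concentration rather than $-\infty$; below-LOQ values are flagged, never
censored, so tables stay total-preserving.

The model assumes a common detection efficiency for standards and
biological templates. Where a taxon's primer match is imperfect its
amplification efficiency is lower and its abundance is *underestimated* by
exactly that factor — this is a property of the method, not of the
implementation, and the simulator reproduces it (a taxon with efficiency
0.21 is recovered at ≈ 21 % of truth).

### Fitting

$b$ and $\theta$ are estimated by alternating profile maximum likelihood:
given $\theta$, the score in $b$ is strictly monotone and solved to
machine precision with `uniroot`; given $b$, $\theta$ is maximized on a log
grid with `optimize` (search range $10^{-4}$–$10^{8}$); the alternation
stops when the log-likelihood changes by less than $10^{-10}$ (at most 100
outer iterations, otherwise an error), and a joint BFGS polish guards
against slow alternation. The moment estimator initializes $\theta$. As
$\theta \to \infty$ the fit reduces to the closed-form Poisson solution
$b = \ln(\sum_i y_i / \sum_i e^{x_i})$; fits that reach the search cap are
flagged `poisson_limit`. The intercept's standard error uses the expected
information $\sum_i \theta\mu_i/(\mu_i+\theta)$ at the fitted values.

The quantification model has no free slope, but a free-slope companion
model is also fitted (via `MASS::glm.nb`, falling back to a Poisson GLM on
failure) purely to report the Wald p-value of the dose coefficient as a
curve-quality diagnostic; it plays no role in conversion.

Each (variant, gradient level) pair contributes one calibration point —
pooling variants within a level is possible by relabelling but separate
points are the default, since the variants are distinct molecules with
their own sequences. Zero-read standards are excluded from the fit but
drive the limit of quantification.

### Unit chain

Volumes enter as a multiplicative chain with the defaults taken from the
standard protocol:

* `mass_to_copies()`: $C = M \times 6.02\times10^{23} / (660 \times 10^9
  \times L)$ copies/µL for a fragment of $L$ bp at $M$ ng/µL.
* `expected_reaction_conc()` / `reaction_to_dna_conc()`:
  $Z = Y \cdot \frac{D}{E}\cdot\frac{F}{G}\cdot\frac{H}{I}$ and its exact
  inverse, with $D/E$ the sample dilution, $F/G$ the sample share of the
  sample+ISG mix and $H/I$ the templating ratio (defaults $1/1$, $3/4$,
  $2.5/50$). The `include_sample_mix` flag drops $F/G$ for templates that
  skip the mixing step (the qPCR variant of the chain).
* `dna_to_sample_conc()`: $X = Y \cdot C/A$ per gram or litre, assuming
  100 % DNA extraction efficiency (exposed as a multiplier, default 1).

The "1:3" standard:sample mixing ratio is read as one volume of ISG mix to
three of sample, i.e. $F/G = 3/4$ for the sample and $1/4$ for the
standards; the opposite reading is available by configuring
`conversion_factors()`. The four-level gradient (4.0×10⁶ … 4.0×10³
copies/µL, equal-volume mixed, total 1.111×10⁶ copies/µL) is the default
`build_spikein_series(4.0e8, c(100, 1e3, 1e4, 1e5))`.

### Limit of quantification

The LOQ is the read level of the lowest gradient level at which the
standards were detected. Aggregation across variants is not prescribed
anywhere authoritative, so this package takes the conservative choice: a
level counts as detected only when *every* variant at that level has reads,
and the threshold is the mean read count across those variants. ASVs below
the threshold keep their concentrations but carry `above_loq = FALSE`.

## ISG design

The designer treats the panel as a constraint problem: for every pair, the
span from the forward site's start to the reverse site's end must equal the
expected product length (500, 531, 491, 465 and 291 bp for the default
panel, lengths counted inclusive of both primer sites); sites sharing a
primer are rigid blocks; all sites must fit in the 615-bp backbone with at
least `min_gap = 1` intervening base. Blocks are placed by deterministic
smallest-coordinate search with backtracking, so any feasible instance
yields the same left-packed layout; positions along the molecule are
otherwise unconstrained and any constraint-satisfying layout is accepted.

Spacers are filled with seeded random bases whose G/C count brings the
whole molecule onto the GC target (0.50 ± 0.05 by default; replacing G/C
with A/T in the gaps is the only degree of freedom, primer sites are
fixed). Every candidate is screened against all panel primers on both
strands at ≤ 2 mismatches — IUPAC-aware, so a degenerate code matches its
whole class — and redrawn on a hit (bounded retries, then an error). The
published standards used fixed spacer fragments from a synthetic 16S
spike-in family; those exact sequences live in supplementary material, so
this package generates seeded random spacers under the same constraints
instead — reproducible from the seed, and original sequences can be
supplied via FASTA wherever templates are accepted. Degenerate positions
inside embedded primer sites are concretized with a fixed first-of-class
policy (A < C < G < T); since in-silico PCR always matches classes, any
policy satisfies binding. Coordinates are 1-based inclusive everywhere.

## QC conventions

* GGC motifs (associated with polymerase inhibition and lagging-strand
  dephasing on the sequencer) are counted overlap-aware on the sense strand
  only, and split at a configurable boundary, default 251 bp — the extent
  of a single-end forward read; a motif starting exactly at the boundary
  counts as "front". Whether both strands or boundary-straddling motifs
  should count differently is not settled; these defaults are documented
  choices, not claims.
* ASV partitioning labels a sequence `ISG` on exact match to a reference
  (truncated to the read length for single-end data), `discard` within 2
  mismatches of a reference (sequencing artefacts of the standards), and
  `biological` otherwise.
* Read-recovery ratios (out/in) and SE-vs-PE increment factors are plain
  quotients computed per category, so category-differential loss (e.g.
  GGC-rich functional genes losing reads in paired-end merging) is visible.

## What the simulator does and does not emulate

`simulate_library()` draws NB read counts with mean
$\mu = \mathrm{DE}\times\mathrm{eff}\times Z$ for every standard and taxon,
with the in-reaction dose $Z$ derived through the same volume chain the
quantifier inverts. Defaults are the recovery-study conditions: four
variants observed along the full four-level gradient (16 calibration
points), detection efficiency 8 reads/copy, NB size 5, and an equimolar
community of 12 taxa at 3.0×10⁴ copies/µL DNA — an equimolar mock-style
design at the mock standard concentration, with a richness modest enough
to keep per-taxon counts interpretable. Sequencer error, chimeras and the
paired-end merge loss are *not* simulated at base level; they are
summarized by the per-taxon efficiency multiplier, because the calibration
model only ever sees counts. Passing recovery tests therefore validates
the statistical chain, not robustness to upstream read-processing
artefacts, taxonomy errors, or real primer-coverage distributions.

With these conditions the package's acceptance suite checks that over 200
simulated libraries the median absolute relative error of the recovered
total concentration stays ≤ 15 % and nominal 95 % intervals from the
intercept SE cover the true intercept ≥ 88 % of the time; both follow from
the NB noise budget (count CV ≈ $\sqrt{1/(k m) + 1/(k\theta)}$ for $k$
equimolar taxa plus intercept SE ≈ 0.11 at 16 points with $\theta = 5$).

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`withr::with_seed`),
so designs, simulations and pipeline outputs are byte-identical across
runs and platforms. The test suite uses 25 design seeds (100 ISG
sequences) for the GC property, 50 random small instances for the
likelihood-grid oracle, and 200 simulated libraries for each of the
recovery and bias-mechanism checks; these sizes give Monte-Carlo error
comfortably inside the asserted margins while keeping the whole suite under
a minute.

## Known limitations

* Quantification inherits primer-coverage bias: taxa poorly matched by a
  primer set are systematically underestimated, and nothing in the
  calibration can detect this from a single library.
* 16S copy numbers per genome are not corrected (rrnDB-style corrections
  are out of scope), so "copies" are gene copies, not cells.
* The designer optimizes layout feasibility and GC only; melting
  temperature, hairpins and primer dimers are not modelled.
* Upstream read processing (trimming, merging, denoising) is consumed, not
  performed; read-flow metrics accept counts from the upstream tool.
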