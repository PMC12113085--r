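---
title: "Blinded validation of segmentation: design, statistics, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded validation of segmentation: design, statistics, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindval)
```

## The problem and the protocol

Segmentation tasks with subjective boundaries — dense tissue in a
mammogram, diffuse pathology, weathered defects — have no single ground
truth: expert annotators disagree with each other (inter-observer
variability) and with themselves over time (intra-observer variability).
Scoring a model against one expert's masks therefore mixes model error
with human inconsistency.

The protocol this package implements separates those ingredients. A set
of $N$ images is annotated by $S$ *sources* (human labelers and/or
models). All $N \times S$ masks are pooled, shuffled, and shown one at a
time to an independent *validator* who does not know which source drew
each mask. The validator assigns one of a small set of labels (by
default *correct*, *oversegmented*, *undersegmented*, *incorrect*) and
may leave a comment. Covertly, for each source a random subset of images
is presented a second time; because the validator cannot tell a repeat
from a first showing, the pairs of judgments on identical stimuli
measure the validator's own consistency. Three kinds of blindness are in
force at review time: to the source, to the repeat status, and to how
many items of each kind remain.

Downstream, labels are *collapsed to binary* — the configured agree
subset versus everything else — and the analysis reports:

* per-source **agreement percentages** over first showings only (so each
  source's denominator is exactly $N$);
* **concordance-stratified DSC**: for each source pair, images are split
  by whether the validator's binary judgment was the same for both
  sources' masks, and the inter-source Dice similarity coefficient
  (DSC $= 2|A\cap B|/(|A|+|B|)$) is summarised per stratum;
* **intra-observer reliability** from the covert repeats: the $k \times
  k$ and binary confusion matrices (rows first evaluation, columns
  second), accuracy with a Wilson interval, Cohen's
  $\kappa = (p_o - p_e)/(1 - p_e)$, balanced accuracy, F1, precision and
  recall;
* **order-of-appearance effects**: agreement by whether a source's mask
  was the first, second, or third version of its image the validator
  saw;
* **session analytics**: maximal runs of consecutive validations with no
  break longer than one hour, with durations, throughput and per-session
  agreement.

## Design choices where the protocol is open

Several points are genuinely under-determined by the protocol; the
package fixes them as follows and exposes a switch where a defensible
alternative exists.

**Empty-versus-empty masks.** `dice()` returns 1 when both masks are
empty: two raters agreeing that there is no target region is perfect
agreement. An empty mask against a non-empty one scores 0 by the
formula. This case never arises in the synthetic cohort (regions are
non-degenerate by construction) but the convention is declared rather
than accidental.

**Interval for mean DSC.** Mean-DSC intervals use the Student-t form
$\bar x \pm t_{1-\alpha/2,\,n-1}\, s/\sqrt n$. At moderate $n$ the
normal-quantile interval is visibly narrower (at $n = 55$ the half-width
differs by about 2%), and the t form is the standard choice for a mean
with estimated variance, so it is used throughout
(`mean_ci_t()`, `dsc_summary()`, `stratified_dsc()`).

**Interval for proportions.** All proportion intervals are Wilson score
intervals (`wilson_ci()`). At the sample sizes and high agreement rates
typical of these studies (e.g. 277/300) the Wald interval is both
miscentred and anti-conservative; Wilson behaves well down to small
counts and is exactly invertible from the score test. A Monte-Carlo test
in the suite checks near-nominal coverage.

**Precision/recall orientation on repeat matrices.** A repeat confusion
matrix has no natural "truth" axis. The package treats the first
evaluation as reference and the second as prediction, with the binary
*agree* class positive. This orientation is asserted in tests via the
published-style metric chains, where it is the only orientation
consistent with the full metric set.

**Ranks and duplicates.** Order-of-appearance ranks are computed over
first showings only, so each image receives exactly the ranks
$1..S$ with no ties; covert repeats are excluded (they feed only the
intra-observer analysis, which keeps the agreement denominator at $N$
per source and the repeat denominator at the duplicate total).
`order_ranks(include_duplicates = TRUE)` provides the inclusive variant
for sensitivity analyses.

**Duplicate placement.** No adjacency constraint is imposed between a
duplicate and its original — the shuffle is a uniform permutation of all
items, which a property test verifies at the distribution level over
2,000 seeds. An optional `min_gap` exists (rejection sampling) but
defaults to off.

**Session boundary.** A new session starts when the gap from one item's
answer to the next item's display *strictly exceeds* the threshold
(default 3600 s); a gap of exactly one hour stays in-session. Duration
runs from the session's first display to its last answer, which makes
single-item sessions well defined (display-to-answer time) without a
special case. Two timestamps are logged per item precisely so that this
anchor exists.

**Kappa degeneracy.** When the marginals make expected agreement
$p_e = 1$, $\kappa$ is undefined; `cohens_kappa()` returns `NA` with a
warning rather than a silent 0. The multi-category matrix uses the same
chance-corrected formula with full marginals and is reported alongside
the binary one.

**Blinding as an artifact boundary.** The schedule builder returns two
separable objects: the *plan* (ordered anonymous 128-bit presentation
tokens — random tokens, not sequential ids, which would leak generation
order) and the *provenance record* (token → image, source, replicate),
sealed to its own JSON file. The on-disk review bundle contains masks
keyed by token and an index whose schema is audited for provenance
fields on read; the pipeline's review stage additionally refuses a
provenance file placed inside the bundle directory. One validator is
served per schedule; independent validators get independent schedules
with independent seeds.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` + `gen_masks()` + `validator_behavior()` +
`simulate_validator()` generate a complete, statistically controlled
study. The defaults are the study conditions the package is built
around: 500 images × 3 sources (`L1`, `L2`, `model`) with 100 covert
duplicates per source — 1800 presentations, 1500 of them first showings —
per-source base agreement probabilities (0.850, 0.828, 0.832), a
repeat-flip probability $\varepsilon = 0.045$ (expected binary
discordance $2\varepsilon(1-\varepsilon) \approx 8.6\%$, matching the
observed intra-observer inconsistency scale of such studies), no order
bias, and 28 work sessions separated by two-hour breaks at roughly 40 s
per item. Masks default to 64 × 64 px.

**Masks.** Each image has a base region: an ellipse with a gentle
harmonic shape modulation, guaranteed non-degenerate. Each source's mask
deforms the base boundary by an independent smooth radial jitter whose
amplitude (in pixels) is the per-source `perturbation`; expected
pairwise DSC decreases monotonically in that amplitude (verified over
200 images in the suite). The generator makes no attempt at anatomical
realism — breast outlines, pectoral muscle, intensity texture are all
absent — because only the *DSC structure* of the catalog reaches any
analysis. Consequently, passing tests demonstrate the statistical
machinery, not performance on real mammograms.

**Validator.** For a first showing of a source at rank $r$, the latent
binary judgment is agree with probability
$\text{base}(s) + \delta_r$, clipped to $[0,1]$ (with a warning if
clipping occurs); a disagreeing judgment draws its category from the
configured split (default 0.50 / 0.35 / 0.15 over oversegmented /
undersegmented / incorrect — *incorrect* is reserved for rare cases, as
review instructions typically demand). For duplicated items the latent
judgment is a property of the item, and *each* of its two evaluations
independently flips across the binary boundary with probability
$\varepsilon$ — hence the $2\varepsilon(1-\varepsilon)$ expected
discordance the parameter-recovery tests check (at $\varepsilon = 0.04$
and 5,000 duplicates, within 3 binomial standard deviations). With
$\varepsilon = 0$ both confusion matrices are exactly diagonal, because
the latent disagree *category* is also per-item. What the model omits:
drift of the validator's criterion over time, fatigue, image-difficulty
heterogeneity, and any coupling between mask appearance and the label —
the simulated judgment depends on the source and rank, never on the
pixels.

**Seeds.** Every stream is derived hierarchically from a master seed via
per-key child seeds, so enlarging `n_images` never reshuffles earlier
images, and (config, behavior, seeds) determine every output byte.

## Numerical conventions and problem sizes

Reported tables round to 3 decimals; computation is at full precision
(percentages are reported on the 0–100 scale). Strata with $n < 2$ are
emitted without an interval and flagged with a warning. The test suite
exercises the design invariants at small scale (permutation uniformity
on a 4-item plan over 2,000 seeds), the parameter recoveries at moderate
scale (3,000–5,000 images, chosen so that 3-standard-deviation binomial
bands are decisive within seconds), and one full-scale synthetic study
(500 × 3 + 300) end to end. The exhaustive 2×2 matrix-recovery search
used in the acceptance chain enumerates all matrices with total 300 and
is exact.

## Known limitations

The review loop ships as a programmable contract (scripted or console
drivers); a graphical interface must honor the same contract but is not
included. Comments are stored verbatim and never analysed. No
multiple-testing correction is applied anywhere: the outputs are
descriptive agreement statistics, not hypothesis tests, and order-effect
trends in particular should be read as exploratory. Aggregation of
multiple annotators into a consensus reference (e.g. STAPLE-style) is
out of scope.
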