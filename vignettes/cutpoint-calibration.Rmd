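---
title: "Calibrating accelerometer intensity cut points against direct observation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating accelerometer intensity cut points against direct observation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

## The measurement problem

Hip-worn accelerometers summarise movement as dimensionless activity
*counts* per epoch. Counts only become interpretable once *cut points* —
count thresholds separating sedentary, light, moderate and vigorous
intensity — have been calibrated against a criterion measure of what the
wearer was actually doing. Cut points are population-specific: children
who move differently (for example, children with intellectual
disabilities and atypical gait) produce different counts during the same
behaviours, so borrowing thresholds calibrated elsewhere introduces
systematic misclassification.

`accelcal` implements a field-calibration design in which the criterion
is momentary time-sampled direct observation (SOFIT student-activity
codes) collected during semi-structured activity sessions:

1. **Reintegration and alignment.** Device counts exported in 10-s
   epochs are summed in consecutive pairs to 20-s analysis epochs,
   matching the observation cadence (10-s observe / 10-s record, three
   codes per minute). Alignment to the observation stream is an explicit
   integer interval offset, making the study's manual video
   synchronisation reproducible. Invalid intervals (child out of the
   hall) and implausibly large counts are screened out with a per-rule
   exclusion report.
2. **Hold-out split.** A fixed number of participants per session
   (default 2) is randomly held out for cross-validation; the draw is
   seeded and stratified by session, and all of a participant's epochs
   move together.
3. **Calibration.** For each intensity the observation codes are
   binarised (sedentary positives {1, 2}; moderate {4, 5}; vigorous
   {5}) and an exhaustive ROC sweep over every distinct observed count
   is run. The operating point maximises Youden's
   $J = \text{sensitivity} + \text{specificity} - 1$; the AUC is the
   rank-sum pairwise probability with a Hanley–McNeil standard error.
   The three thresholds are assembled hierarchically: the vigorous lower
   bound minus one is the moderate upper bound, and light is the
   residual band between the sedentary and moderate boundaries.
4. **Cross-validation.** Held-out epochs are classified and compared to
   the criterion per intensity: sensitivity, specificity, total
   agreement, and Cohen's kappa with its large-sample (Fleiss–Cohen–
   Everitt) standard error, labelled on the Landis–Koch scale.

## Conventions that matter

* **Thresholds are observed count values** with inclusive comparisons
  (sedentary positive when `counts <= t`; moderate/vigorous when
  `counts >= t`), matching how published boundary tables are written.
  Candidate thresholds are the observed distinct counts plus the two
  degenerate endpoints, not midpoints; the alternative (midpoints) can
  shift a boundary by one count unit.
* **Ties in J** are broken towards higher sensitivity (the screening
  convention), then towards the more inclusive threshold; the applied
  tie-break is recorded on the result.
* **Units.** The unit of record is counts/20-s; counts per minute are
  the boundary times three. The moderate *upper* bound in cpm is defined
  as `vigorous_lower_cpm - 1` so that published ranges remain contiguous
  on the cpm scale — note this differs by 2 from three times the 20-s
  moderate upper bound. Four-way classification in the two unit systems
  agrees on all integer 20-s counts because no multiple of three falls
  in the 1-cpm gap.
* **MVPA** is not a fourth ROC: binarising with positives {4, 5} *is*
  the MVPA-versus-rest analysis, so the MVPA boundary coincides with the
  moderate lower boundary.
* **The moderate agreement row** compares predicted-moderate-only
  against criterion positives {4, 5} by default; since truly vigorous
  epochs are criterion-positive but predicted vigorous, its sensitivity
  is structurally capped below 100% whenever vigorous activity occurs.
  `moderate_includes_vigorous = TRUE` switches to the alternative
  pairing in which predicted vigorous epochs also count positive; both
  views are legitimate and the package reports whichever is requested.
* **AUC confidence intervals** use the Hanley–McNeil standard error with
  a normal 95% interval clipped to [0, 1] — a closed-form, testable
  choice; bootstrap or exact methods would be drop-in replacements.

## The synthetic-session generator

Because raw calibration studies are rarely deposited, the package ships
a generator that emulates the statistical structure such a study
produces, and which doubles as the test bed:

* **Session protocol.** A phase plan (default: warm-up 10 min,
  instruction games 10 min, obstacle games 10 min, team games 15 min)
  gives each phase a target mix over the five SOFIT categories. Within a
  phase, behaviour is semi-Markov: categories drawn from the mix with
  geometric bout dwell times (default mean 15 s, a plausible bout length
  for children's sporadic activity), so occupancy converges to the mix.
  The default seven sessions of (8, 8, 9, 7, 7, 5, 6) participants give
  a 50-child study; holding out two per session leaves 36 for
  calibration and 14 for cross-validation.
* **Count emission.** No published per-category count distributions
  exist, so emission is lognormal per category — right-skewed,
  nonnegative, two parameters. Default 10-s vertical medians are
  (5, 55, 120, 250, 520) counts with a common `sdlog` of 0.9: category
  medians bracket published 20-s boundaries for children on this device
  family, and the implied class overlap puts discrimination in the
  AUC ≈ .86–.94 range that field calibrations report. Each 10-s window
  takes the category occupying most of its seconds (ties to the later
  bout); a per-participant lognormal multiplier (mean 1,
  `sdlog = 0.15`) adds between-child heterogeneity; vector magnitude is
  the vertical count times `1 + lognormal` (never below vertical).
* **Observation.** One code per 20-s interval, sampled at the final
  second of the observe window; a transition at that instant records the
  higher code. Observer error replaces a code with an adjacent category
  (default probability 0.10, consistent with ~90% single-rater
  reliability; confusions between neighbouring intensities are the
  plausible error mode). Intervals are flagged invalid with probability
  0.02. Traces that do not fill a whole interval are truncated, and an
  odd trailing 10-s epoch is dropped rather than zero-padded, which
  would bias the final interval downward.

What the generator does **not** emulate: raw 30 Hz waveforms, nonwear
and free-living behaviour, aetiology-specific movement differences, and
any systematic (non-random) observer bias. Passing tests on synthetic
sessions therefore demonstrate that the *analysis machinery* is correct
under the stated statistical structure, not that the default parameters
reproduce any particular cohort.

## The analytic threshold oracle

For testing, `analytic_optimal_threshold()` computes the exact
Youden-optimal threshold implied by a configuration: per-category pmfs
of rounded lognormals (participant multiplier folded in analytically)
are self-convolved to 20-s sums, mixed with the marginal category
occupancy pushed through the adjacent-mislabelling kernel, and the
optimum is found by exhaustive search over the integer support, with
plateau midpoints (so perfectly separated classes return the gap
midpoint with $J = 1$). The oracle deliberately models the *idealised*
mixture — one category per interval, two independent 10-s draws — and
not the generator's within-interval category mixing, majority-window
emission or transition rule. It is restricted to the vertical axis:
the vector-magnitude factor applies after integer rounding, which has no
tractable closed form.

This idealisation is visible in the package's recovery diagnostics
(`scripts/acceptance.R`): on ~10,000-interval studies with 60-s bouts
and 5% mislabelling, the empirical Youden threshold scatters around the
analytic optimum with a median absolute error of roughly 10–20 counts —
the expected cube-root-rate sampling noise of an argmax estimator, far
larger than the spacing of adjacent observed counts — and empirical AUC
sits ~0.02–0.03 below the analytic value because mixed intervals blur
the class-conditional distributions. Both effects are properties of the
estimator and the generative process, not defects of the sweep: on
draws taken directly from the oracle's own mixture, empirical J and AUC
match the analytic values within sampling error, and the sweep itself is
verified exactly against brute-force enumeration.

## Numerical and degenerate-input choices

* Self-convolutions pad the FFT to a power of two (awkward transform
  lengths degrade R's mixed-radix FFT to quadratic time).
* A category may be made degenerate at zero counts with
  `meanlog = -Inf`.
* Identical class distributions raise "no discriminating threshold"
  rather than returning an arbitrary value; single-class label vectors,
  empty margins (sensitivity undefined), and degenerate kappa margins
  (`pe = 1`) are all explicit errors or flagged `NA`s, never silent
  zeros.
* Problem sizes used by the test suite were chosen to keep every check
  sharp at interactive scale: exhaustive-oracle equivalence on 200
  random instances of up to 500 epochs, distribution-level oracle checks
  at 50,000 draws, and recovery studies of 20 seeds at ~10,000 intervals
  each.

## Known limitations

* Calibration quality on real data is bounded by the criterion: SOFIT
  codes walking as moderate regardless of pace, does not capture
  extraneous movement, and the standing-as-sedentary question is
  unresolved in the field; the binary coding scheme is configurable but
  the default follows the conventional table.
* Agreement is computed on pooled epochs, not per-participant averages;
  participants contributing more epochs weigh more.
* The kappa standard error is the large-sample formula; it is accurate
  for the epoch counts typical of calibration studies but optimistic for
  very small held-out sets.
* Vector-magnitude calibration has no analytic oracle; its correctness
  is established through the same sweep machinery and perfect-separation
  constructions as the vertical axis.
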