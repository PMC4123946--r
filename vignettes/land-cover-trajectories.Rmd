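---
title: "Land-cover trajectory analysis: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-cover trajectory analysis: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcctraj)
```

## The problem

Tropical deforestation frontiers are not a one-way conversion of mature
forest (MF) to non-forest (NF). Cleared land is used for crops or pasture
for a few years, abandoned to regenerating secondary forest (SF), and
often recleared. Understanding carbon balance, land-use intensity and
regeneration potential requires reconstructing this cycle pixel by pixel
from decades of classified satellite maps — typically Landsat time-series
with irregular 1–4 year gaps between usable scenes.

`lcctraj` takes a dated stack of categorical maps over the alphabet
{MF, NF, SF, WATER, NODATA} and derives: temporally consistent label
sequences, per-pixel land-use history metrics, annualised change rates and
their typology, and misclassification-calibrated area estimates. A
semi-Markov landscape simulator with exact ground truth makes every stage
testable end to end without any satellite data.

## Data model

A `classified_stack` is an ordered sequence of co-registered
`land_cover_map`s with strictly increasing day-resolution dates. Time
between acquisitions is measured in decimal years (day count / 365.25),
because dates are day-resolved and all rates are per calendar year. Open
water is a *permanent common mask*: the union of WATER cells over all
dates is imposed on every date. NODATA (cloud) is per-date. One refinement
mirrors operational practice: where a cloud-free recent-image mask asserts
that MF persisted throughout the series, earlier NODATA cells under the
mask are filled as MF (`fill_cloud_gaps()`); cloud over NF/SF is retained
as NODATA and those cells are simply excluded from that date's areas.

Codes are fixed small integers (0 WATER, 1 MF, 2 NF, 3 SF, 255 NODATA) so
file round-trips are bit-exact. Map I/O uses a small headered ASCII grid
format plus CSV manifests; the computations are grid-based and make no use
of georeferencing.

## Temporal-consistency correction

Classifiers confuse old SF with MF, producing implausible SF/NF → MF
reversions over observation gaps. `correct_disallowed_transitions()` scans
date pairs chronologically and relabels any MF that follows SF or NF as SF
— never NF, since NF/MF spectral confusion is assumed unlikely. The scan
is sequential, so corrections propagate forward; we prove by exhaustive
enumeration (all 5-code sequences up to length 7, in the test suite) that
the single pass reaches the same fixpoint as rescanning until stable.
NODATA dates are skipped when locating the previous label.

## Trajectory metrics

For each pixel and date (after correction):

* **ASF** — age of secondary forest: decimal years since the onset of the
  current uninterrupted SF run. The onset is the *first date the new state
  is observed*; events occur somewhere inside the preceding gap, so ages
  are conservative minimum ages. SF present since the first date has an
  unknown abandonment date: the age is censored (`asf_censored`).
* **PALU** — period of active land use: duration of the NF run
  immediately preceding the current SF run. SF-since-first-date pixels get
  PALU 0 with `palu_zero` set. A direct MF→SF label change (clearance and
  abandonment inside one gap) also yields PALU 0, without the flag.
* **FC** — frequency of clearance: cumulative count of observed MF→NF or
  SF→NF transitions. Pixels entering the series as NF with no later
  clearance are flagged (`fc_nf_start`) and belong to the low FC class for
  binning, since their (unobserved) initial clearance happened before the
  series began.

Runs continue across NODATA dates when the same label resumes; a change
across a gap is dated at the first post-gap observation. Bins are stated
in whole years, so decimal ages are floored before binning: ASF initial
(≤5) / intermediate (6–15) / advanced (≥16); PALU short (≤2) / medium
(3–4) / long (≥5); FC low (≤1) / medium (2) / high (≥3).

Whether durations should accumulate in image-years or calendar-day years
is genuinely open; we accumulate decimal years and floor at binning time,
which is exact for annual series and conservative for gappy ones. The
site-level "onset of SF" used to index the class-share curves is the first
date with any *non-censored* SF: censored first-date SF contributes to
shares but cannot date the onset.

## Change rates

Between consecutive dates, cross-tabulated transition areas (cells NODATA
at either date excluded) feed four processes: MF deforestation (MF→NF),
SF deforestation (SF→NF), their total, and regrowth (NF→SF). Absolute
rates are always R = T/Δt (ha yr⁻¹), so R·Δt recovers the transition area
exactly.

Relative rates come in two conventions, both exposed:

* `ln_area`: r = (100/Δt)·ln(A₂/A₁) on the source-class areas — the
  standardised compounding rate, exact for MF loss;
* `transition_fraction`: r = 100·T/(A_source(t₁)·Δt) — the cleared (or
  regrown) fraction of the source area per year.

The default (`mixed`) uses `ln_area` for MF and total deforestation and
`transition_fraction` for SF reclearance and regrowth. Published
frontier-site summaries report SF-clearance and regrowth rates well above
100 % yr⁻¹, which a pure log-area rate on a surviving class cannot produce
but a per-source-area transition fraction over a short interval can; since
the exact normalisation behind such published values is ambiguous, neither
convention is asserted as canonical and the regrowth denominator
(A_NF(t₁) by default, A_SF(t₁) optionally) is configurable. Summaries
(min/max/mean/median/IQR/sd) use type-7 quantiles, report magnitudes, set
sd = 0 with a flag for single records, and count undefined
(zero-denominator) rates in a QC column.

Each period is labelled on two orthogonal axes of the dynamics typology:
clearance composition — (a) MF only, (b) MF > SF, (c) MF < SF, (e) SF
only, with "little or no" meaning below 1 % of the larger clearance term
(no threshold is stated in the published typology; 1 % is our declared
choice) — and clearance/regrowth balance — (d) net clearing vs (f) net
abandonment. Exact ties go to (b) and (d) with a tie flag, for
deterministic output.

## Accuracy and inverse calibration

Error matrices are oriented rows = reference, columns = classified;
overall accuracy is trace/n, omission errors are row-wise, commission
errors column-wise. The validation design samples each class at centroids
of distinct large patches (4-connected components above an area
threshold, default 6 ha); concave patches fall back to the nearest patch
cell to the centroid.

Naive pixel counting is biased under misclassification. The inverse
(Tenenbein) estimator revises the counted proportions with the
conditional reference-given-classified probabilities:

π̂ᵢ = Σⱼ (nᵢⱼ/n·ⱼ)·pⱼ,  pⱼ = (n·ⱼ + fⱼ)/N,

with fⱼ the map pixels classified j outside the validation sample and
N = n + Σfⱼ. Calibrated proportions are nonnegative and sum to 1 by
construction; with a diagonal matrix the calibration is the identity. The
pipeline treats the patch-centroid validation points as a simple random
sample — a documented approximation; whether the original analyses
excluded validation pixels from the map counts is not decidable from the
published description, and with N ≫ n the two readings agree to < 0.1 %.

## The simulator: what it emulates, and what not

`simulate_stack()` evolves each pixel independently in continuous time:
MF persists against a clearance hazard, NF lasts an integer number of
years drawn from the active-use distribution, SF faces a reclearance
hazard restarting NF. Per-year probabilities p convert to hazards
λ = −log(1−p), so the event probability over a gap of Δt years is
1−(1−p)^Δt — consistent across irregular gaps. A certain event (p = 1)
occurs just after the phase starts rather than exactly at it, so the
starting state remains observable. The chain is then sampled at the
acquisition dates, which reproduces minimum-age censoring naturally:
events between acquisitions are dated at the next observation.

Defaults are a stated world resembling a Rondônia-style frontier and are
not tuned: 21 irregular dates 1984–2011 (1–3 yr gaps), initial mix
91 % MF / 1 % NF / 9 % SF, MF clearance hazard 0.04 yr⁻¹ (reproducing the
observed decline of MF from ~91 % to ~32 % over 27 years at such sites),
geometric active-use duration with mean 2 years (most published PALU ≤ 2
years), SF reclearance hazard 0.15 yr⁻¹ (within the published range of SF
clearance rates), 0.09 ha pixels, and a 2-cell WATER border strip to
exercise the common-mask path. Classification noise is injected per cell
from a row-stochastic confusion matrix; the bundled example rows mirror a
published frontier-site assessment in which SF is the hardest class.

Ground truth is traced from the discretised state sequence by an
independent per-pixel reference implementation of the metric definitions;
the vectorised production code must reproduce it exactly, at every
pixel-date, in the tests.

The simulator does *not* model spatial autocorrelation of clearings
(pixels are independent; the spatial grain of real clearance is not
calibrated here), spectral reflectance, fire scars, or temporally
correlated classification errors. A green simulation test therefore
establishes algorithmic correctness of the trajectory accounting and
estimator behaviour under independent noise — not realism of landscape
pattern, nor classifier performance on real imagery.

## Numerical choices

* Decimal years = days/365.25 everywhere; no fractional-date arithmetic.
* Confusion rows must sum to 1 within 1e-12; calibrated proportions sum
  to 1 within 1e-9 in all checks.
* Degenerate inputs: empty predicted columns abort calibration naming the
  class; zero source areas flag rates undefined rather than emitting
  ±Inf; a zero inside-mask deforested fraction yields an explicitly
  flagged infinite incidence ratio.
* All stochastic code paths take explicit integer seeds and are
  bit-reproducible.

## Known limitations

* Clearance and abandonment falling inside a single observation gap are
  invisible (MF→SF label changes), deflating FC and PALU; this is
  inherent to post-classification analysis at these revisit intervals.
* ASF/PALU at the series edges are censored minimum values, not ages.
* The correction rule trusts SF/NF labels over MF labels; a genuine
  MF-labelling error *before* a spurious SF label is made permanent.
* No variance or confidence intervals accompany calibrated areas; the
  published method reports none, and a bootstrap would be a natural
  extension.
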