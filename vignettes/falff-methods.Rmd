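---
title: "Regional fALFF analysis of hypertensive and normotensive cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional fALFF analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falff)
```

## The measurement model

Resting-state BOLD fluctuations in the low-frequency range carry a mixture
of neuronal, vascular and artefactual signal. The amplitude of
low-frequency fluctuations (ALFF) of a voxel time series $x_t$,
$t = 1, \dots, N$, sampled at repetition time $\mathrm{TR}$, is defined
here on the one-sided periodogram. Writing $X_k$ for the DFT coefficient
at bin frequency $f_k = k/(N\,\mathrm{TR})$, $k = 1, \dots,
\lfloor N/2 \rfloor$, the per-bin power is $P_k = |X_k|^2 / N$, a scaling
under which Parseval's identity reads (interior bins counted twice, the
Nyquist bin once for even $N$)
$$\sum_k w_k P_k \;=\; \sum_t (x_t - \bar x)^2 .$$

ALFF over a band $B = (f_\mathrm{low}, f_\mathrm{high}]$ is the mean
amplitude $\frac{1}{|B|}\sum_{k \in B} \sqrt{P_k}$, and fractional ALFF is
$$\mathrm{fALFF}(B) \;=\;
  \frac{\sum_{k \in B} \sqrt{P_k}}{\sum_{k \in (0,\,f_\mathrm{Nyq}]} \sqrt{P_k}},$$
the in-band fraction of total amplitude. Because numerator and denominator
are both bin sums, this equals the ratio of bin-count-weighted mean
amplitudes: the "mean amplitude" formulation and the sum formulation are
the same statistic, and `alff(..., bins = "all")` exposes the
mean-over-all-bins variant whose constant factor cancels in the fraction.
fALFF lies in $[0, 1]$, is invariant to positive rescaling of the series,
and sums to 1 over any partition of $(0, f_\mathrm{Nyq}]$ into disjoint
bands. A voxel whose spectrum is identically zero has no defined fraction
and is propagated as missing.

Three conventions are fixed deliberately:

* **DC exclusion.** The spectrum lives on the $\lfloor N/2 \rfloor$
  positive bins only. Linear detrending drives the DC coefficient to
  (numerically) zero, and a band written "0--0.1164 Hz" is then
  well-defined as the half-open interval $(0, 0.1164]$.
* **Half-open band membership** $(f_\mathrm{low}, f_\mathrm{high}]$ on bin
  centres, so that the broad (0--0.1164 Hz), narrow (0.01--0.08 Hz) and
  full bands partition cleanly and the additivity invariant is exact
  rather than approximate.
* **Ideal spectral masking** instead of an FIR/IIR filter. The band edges
  are exact specifications and no filter order is given; with an ideal
  mask, filtering followed by the periodogram is *identical* to masking
  the periodogram, so the pipeline computes one transform per participant
  and the numerator/denominator of fALFF are mutually consistent by
  construction.

At the acquisition geometry used throughout (490 timepoints, TR 0.735 s)
the bin spacing is $1/360.15\ \mathrm{s} \approx 0.00278$ Hz, the Nyquist
limit is $1/(2 \times 0.735) = 0.680$ Hz, and the broad band holds 41 of
the 245 bins -- hence the flat-spectrum (white-noise) expectation
$\mathrm{fALFF} \approx 41/245 \approx 0.167$ that the test suite checks.

Why the *fractional* amplitude: a CSF voxel carries large pulsatile power
at every frequency. Its raw ALFF is therefore high, but its spectrum is
flat, so dividing by total amplitude suppresses it relative to parenchyma
whose power concentrates in the low-frequency band. This
high-ALFF/low-fALFF signature is asserted both on constructed spectra and
end-to-end on simulated voxels.

## Standardisation and regional aggregation

Each participant's fALFF map is converted to z-scores against that
participant's own frontal grey-matter reference region: subtract the
reference mean, divide by the reference standard deviation (sample, $n-1$;
the population/sample distinction is negligible at realistic ROI sizes but
must be fixed for reproducibility). Standardising within participant
against an anterior-circulation reference preserves sensitivity to
anterior--posterior differences, which is the comparison of interest.
Regional values are arithmetic means of z over each named region's voxels,
with missing voxels excluded and an all-missing region flagged rather than
dropped.

The default region set has 15 analysis regions -- midbrain, pons and
medulla (the brainstem subdivisions), bilateral amygdala, hippocampus,
thalamus, insula and visual cortex, midline hypothalamus, and a
precentral-gyrus cortical control -- plus the frontal grey-matter
reference and a CSF compartment that never enters the ANCOVA. Fifteen
levels makes the region factor contribute 14 numerator degrees of freedom,
matching the reported design; the exact lateral composition is not
enumerated in the source design, so this set is a documented choice.

## Cohort construction

Hypertension is confounded with age, sex and BMI, so group comparisons
require matched cohorts. The propensity score is fitted by logistic
regression of group on age, sex (coded male = 1) and BMI; matching is
greedy 1:1 nearest-neighbour on the logit of the propensity, without
replacement, treated units in descending propensity order with ties broken
by id -- the documented default behaviour of the standard matching
software this emulates. No caliper is applied by default; a donor-pool
that runs out simply leaves treated unmatched with a warning, which is how
a design can end with fewer matched controls than treated. Balance is
reported as group means, Welch t-tests (continuous), a Pearson chi-square
without continuity correction (sex), and standardised mean differences
with the $\sqrt{(s_1^2 + s_2^2)/2}$ denominator conventional in the
matching literature.

## Inference

The regional table (one row per matched participant per region) is
analysed by a two-way ANCOVA: response `mean_z`, factors group (2 levels)
and region (15 levels), their interaction, and age, BMI and sex as
covariates, ordinary least squares with **Type-II sums of squares**
(order-invariant, marginality-respecting; a config switch exposes
sequential Type I). Effect sizes are partial
$\eta^2 = SS_\mathrm{term} / (SS_\mathrm{term} + SS_\mathrm{residual})$,
invariant to affine rescaling of the response. Three analyses form the
roster -- a seeded small-sample subset in the broad band, and the full
matched cohort in the broad and narrow bands -- and their group and
interaction terms are judged at the Bonferroni-corrected level
$\alpha = 0.05/3 \approx 0.0167$.

Rows are treated as independent observations even though the fifteen
regional values of one participant share that participant's reference
statistics and any global physiology. This reproduces the original
analysis design exactly and is deliberately not "fixed" (a mixed-model
extension is out of scope). The consequences are measurable and worth
understanding. The shared reference *mean* acts as a participant random
intercept with variance $1/n_\mathrm{ref}$ on the z scale, which makes
the pooled-residual interaction test mildly conservative (empirical size
$\approx 0.04$ at the reference design with an 80-voxel reference) and
would make it severely so if the reference were small. The shared
reference *standard deviation* acts as a multiplicative factor aligned
with the regional profile; it only matters when regional z-means are far
from zero. With the default amplitude profile -- analysis regions within
about one z-unit of the reference, mirroring the scale of regional
variation the measured z-profiles exhibit -- both effects are small, the
residual variance is nearly homogeneous across regions, and the classical
noncentral-F power model describes the pipeline well. (A wider profile
places the lowest-amplitude region several z-units out, visibly
heteroscedastic; the compressed profile is the faithful regime.)

Power for a term with $u$ numerator df in a model that also spends $v$
df on other factor terms and $c$ on covariates, at total sample size $n$,
uses noncentrality $\lambda = f^2 n$ (Cohen's $f$) and denominator df
$n - u - v - c - 1$:
$\mathrm{power} = P\{F'_{u,\,n-u-v-c-1}(\lambda) > F_\mathrm{crit}\}$.
`required_n()` inverts this by bracketed bisection, returning the smallest
integer $n$ reaching the target power; the inversion is validated against
an exhaustive scan, and the power values against a raw simulation of the
noncentral F from normal and chi-square draws. The sample-size figure the
original design derived from its pilot (3461) depended on unprinted
calculator inputs, so the implementation is validated against its own
oracles rather than that number.

## The synthetic-data generator

`simulate_cohort()` draws ages and BMI from group-dependent normals, sex
from group-dependent Bernoullis and blood pressures from the group means
and spreads of the published baseline table (systolic 149.0 ± 18.1 vs
137.0 ± 17.0 mmHg, diastolic 87.0 ± 10.6 vs 81.2 ± 9.7; age 57.7 ± 6.7,
BMI 27.8 ± 4.0, 60 % male in the hypertensive group). The normotensive
*pool* is shifted by default (-3 years, -1.5 BMI, -10 percentage points
male) so that the raw groups are confounded and matching has work to do;
the shift sizes are a realistic-confounding choice, not published values.

`simulate_voxels()` builds each voxel as a sum of interpretable parts:

* a **neuronal** component: white Gaussian noise spectrally shaped into
  0.01--0.08 Hz by ideal masking (exact band control with a trivial
  oracle, in preference to AR filtering), normalised to unit sd and scaled
  by the region's amplitude -- base + group delta (+ region-specific
  interaction delta) for hypertensive participants;
* **drift** below 0.01 Hz (shaped noise, sd 0.5);
* **cardiac** contamination: a sinusoid at 1.0 Hz (60 bpm), which lies
  above the 0.680 Hz Nyquist limit and is therefore folded to its alias at
  0.3605 Hz -- the mechanism by which pulsatile signal enters this
  acquisition; a **respiratory** sinusoid at 0.25 Hz; both with random
  phase, snapped to the nearest DFT bin so a frequency requested on a bin
  edge is well-defined;
* **white thermal noise** (sd 1.0);
* CSF voxels: the whole mixture scaled by the broadband multiplier
  (default 5), with a weak neuronal base (0.6), giving the flat, bright
  spectrum that the fractional correction must suppress.

Default amplitudes place the analysis regions 0.01--0.06 units below the
1.5 reference, which after standardisation yields regional z-means in
roughly $(-0.6, 0)$ with per-region sds near 0.6 -- the order of magnitude
the measured z-profiles show. The default group delta (0.002, about
0.03 residual sd) keeps the no-interaction default in the tiny-effect
regime; simulations that need detectable interactions pass larger deltas
explicitly (the reference recovery suite uses a medulla delta of 0.05,
chosen by pilot simulation to give high power at the large design size).

Everything is integer-seeded and deterministic: identical config + seed
give identical cohorts, voxels and study reports. In replicated designs
each participant consumes the seed `base + index`, and replicate base
seeds must be spaced wider than the participant count (the batched helper
and all shipped simulations space them by 1000) so that replicate streams
never overlap.

What the generator does *not* emulate: hemodynamic response shapes, head
motion, multi-site scanner effects, spatial autocorrelation between
voxels, or registration error. Passing tests therefore demonstrate the
statistical machinery -- spectral estimation, standardisation, matching,
inference -- under a known, idealised signal model, not robustness of the
measurement to real-scanner artefacts.

## Problem sizes and numerical choices

The shipped simulations are scaled-down study designs chosen to exercise
every stage with useful Monte-Carlo precision: analysis regions of 4
voxels with an 80-voxel reference rather than anatomical sizes;
null-calibration runs of 200--300 replicates at 40 participants; power
runs of 40 replicates at 34
and 232 participants (510 and 3480 participant-by-region rows, bracketing
the design's pilot and large-scale row counts); matching diagnostics over
200 replicates of 100 treated against a 400-strong donor pool, the
pool-to-treated ratio reflecting selection from a much larger biobank.
Spectral tolerances: direct-DFT agreement 1e-10, Parseval 1e-6 relative,
scale-invariance and band-additivity 1e-10, default 1e-8 elsewhere.
Degenerate inputs are handled explicitly: zero-spectrum voxels become
missing, a zero-variance reference is an error, a perfectly fitting ANCOVA
response falls back to an internal nested-model Type-II table (infinite F,
zero p), and separation in the propensity model is a diagnosed error
rather than a silent extreme fit.

## Known limitations

* The rows-as-independent ANCOVA mis-sizes tests relative to a
  repeated-measures analysis: the shared standardisation makes the
  interaction test mildly conservative (empirical size ≈ 0.04 at the
  reference design) and the group test correspondingly liberal; a
  mixed-model analysis would be the remedy but is deliberately out of
  scope.
* Greedy nearest-neighbour matching is order-dependent by construction;
  optimal matching is not implemented.
* The power model treats the design as a fixed-effects F test with
  independent observations; its predictions are accurate for the shipped
  generator in the homoscedastic default regime and degrade as
  within-participant correlation grows.
* Real-data mode assumes co-registered, preprocessed inputs; no motion
  correction, smoothing or registration is performed.
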