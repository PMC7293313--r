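---
title: "From inter-beat intervals to coping-style inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From inter-beat intervals to coping-style inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copingHRV)
```

## The scientific problem

Stress-coping styles place individuals on a proactive-reactive axis:
proactive animals are routine-forming, behaviourally inflexible and
sympathetically dominated; reactive animals respond to their environment and
are parasympathetically dominated at rest. Resting heart-rate variability
(HRV) indexes this axis physiologically: low resting HRV marks proactive
copers, high resting HRV reactive ones. In a capital breeder such as the
grey seal, where a mother finances lactation entirely from stored reserves
while fasting, coping style can be related to clean, mass-balance measures
of reproductive expenditure and short-term fitness.

`copingHRV` implements the full chain: cleaning raw inter-beat-interval
(IBI) telemetry, deriving resting HRV as the median RMSSD of retained 300-s
resting windows, estimating its across-year repeatability, computing four
mass-based performance metrics and their annual deviance moduli, and fitting
AICc-selected Gaussian mixed models that ask whether reactive mothers
*deviate more* from the annual mean than proactive mothers — a variance
question posed through the deviance modulus rather than a mean effect.

## IBI cleaning

Field telemetry produces three artefact families:

* **Missed beats** — two true IBIs fused into one erroneously long value.
* **Extra beats** — one IBI split into two erroneously short values.
* **Flats and stairs** — device failure runs of invariable or monotonically
  ramping IBIs that cannot be corrected, only flagged.

`correct_artefacts()` uses a running local median *m* (11 beats by default)
with acceptance band `[0.7 m, 1.3 m]` intersected with absolute bounds
250–3000 ms. An extreme long IBI is replaced by `round(ibi / m)` equal
sub-intervals; an extreme short IBI is merged with the following (preferred)
or preceding beat when the sum falls back inside the band. Both operations
conserve the summed duration exactly, every event is ledgered, and the
filter is idempotent: a corrected trace passes through unchanged. The window
size and band factors are conventional values for RR-series cleaning and are
fully configurable; traces shorter than the median window are returned
uncorrected with a flag rather than half-cleaned.

`detect_flat_stair_runs()` reports maximal runs. Flats are runs of at least
3 IBIs equal within a tolerance (default 0: exact equality at the device's
1-ms precision). Stairs are strictly monotone runs of at least 4 IBIs with
equal successive steps; the step tolerance also defaults to 0 because
device-generated stairs interpolate with identical quantized increments,
and because a looser tolerance (e.g. 2 ms) lets chance monotone runs in
genuinely noisy traces contaminate a third of all windows, which would make
the 5% flat/stair filter bite on clean data. Both detectors are verified
against a brute-force enumeration of all maximal runs.

Windows are half-open `[300k, 300(k+1))` segments; an IBI belongs to the
window containing the R-peak that *ends* it, so a beat ending exactly on a
boundary starts the next window and every beat lands in exactly one window.
Recording gaps longer than 5 s split a trace into segments with independent
windowing, so telemetry dropouts cannot fabricate long IBIs. A window is
retained only when at least 95% of its IBIs are Resting, no IBI carries a
high-energy state (locomotion, aggression), at most 5% of IBIs sit in
flat/stair runs, and at most 5% were touched by correction. The corrected
fraction is tracked separately from the flat/stair fraction because the two
filters answer different questions (how much was repaired vs how much is
unrepairable); each has its own threshold.

## Resting HRV

RMSSD — `sqrt(mean(diff(ibi)^2))` within a window, never across window
boundaries — is the time-domain HRV measure used throughout; it is robust
to respiratory cycling under free-running conditions. A seal-season's
resting HRV is the *median* RMSSD over its retained windows (seasons with
fewer than three windows are kept but flagged), and an individual's
coping-style covariate is the median of its seasonal values across years.
Medians of even counts are midpoints of the central pair. For white IBI
noise with standard deviation *s*, `E[RMSSD^2] = 2 s^2`; this closed form
anchors the generator tests.

## Repeatability

Population repeatability is estimated from the Gaussian random-intercept
model `hrv ~ n_measures + (1 | id)` fitted by REML, restricted to mothers
with at least two seasons; `R = sigma2_alpha / (sigma2_alpha + sigma2_eps)`.
The number-of-measures covariate guards against sampling-effort artefacts.
Confidence intervals are percentile intervals over parametric-bootstrap
refits (simulate from the fitted model, refit, recompute R; 1000 draws by
default, reducible for speed). The likelihood-ratio test against the
no-random-effect model uses ML fits for both models and the 50:50 boundary
mixture of a point mass at zero and chi-square(1), i.e. half the chi-square
tail probability, because the ID variance is tested on its boundary.

Per-individual repeatability divides `sigma2_alpha` by
`sigma2_alpha + s2_i`, where `s2_i` is the sample variance of individual
*i*'s *conditional* (BLUP-adjusted) residuals — the within-individual
scatter after removing the individual's own intercept. Marginal residuals
are a defensible alternative; conditional residuals were chosen because the
quantity is explicitly the residual variance *for each individual*, and the
choice is switchable by passing other residual groupings to
`individual_Ri()`.

## Performance metrics and deviance moduli

From the two lactation captures: maternal daily mass loss rate
`MDML = (m1 - m2) / (t2 - t1)`, pup daily mass gain rate
`PDMG = (p2 - p1) / (t2 - t1)`, maternal post-partum mass
`MPPM = m1 + MDML * (t1 - birthdate)` (linear extrapolation to parturition),
and mass transfer efficiency `MTE = MDML / PDMG`, undefined when the pup did
not gain mass. The deviance modulus of each metric is
`|x_i - mean(x in the same year)|`; annual rather than grand means absorb
between-season differences in colony conditions. Records in singleton years
get modulus zero and a degeneracy flag.

Before modelling, responses are z-transformed with the sample (n-1) SD over
the whole analysis table; deviance responses are first log-transformed
(natural log, configurable) with offset `eps = 0.01` in the metric's units
because a record can coincide exactly with its annual mean. The order is:
modulus on the raw scale, then log, then z.

## Mixed-model inference

Each of the eight responses gets a global Gaussian random-intercept model
with fixed terms: individual resting HRV, birthdate, pup sex, year, device
type, maternal post-partum mass (except when MPPM or its deviance is the
response) and the HRV x year interaction. All term subsets respecting
marginality are fitted — 80 candidates for the full global model, 40
without the mass covariate.

Numerical and procedural choices, each of which was genuinely open:

* **ML for selection, REML for reporting.** REML likelihoods are not
  comparable across fixed-effect structures, so AICc ranking uses ML fits
  and the retained best model is refitted by REML for coefficients and
  variance shares.
* **Parameter count.** `k` counts fixed coefficients plus both variance
  components, so the null model has `k = 3` and, e.g., a year + birthdate +
  mass model has `k = 9`.
* **Confidence set.** Keep models within 6 AICc units of the best, then
  discard any model that fails to beat (strictly or by tie) a simpler model
  nested within it. Pruning decisions are made against the fixed
  preliminary set, which makes the result provably independent of
  processing order. The sentence defining the rule can be read in the
  opposite direction (discard simple models beaten by their supersets);
  that literal reading is available via `direction = "literal"` but the
  default follows the established usage, which exists precisely to remove
  overly complex models. The null model is always reported alongside the
  set. Akaike weights are normalized over the full candidate set (the
  normalization set is otherwise ambiguous); weights therefore do not sum
  to 1 within a confidence set.
* **Singular fits are retained in selection.** A boundary estimate
  `sigma2_alpha = 0` is a legitimate ML solution, and several responses
  (pup growth deviance in particular) genuinely carry almost no ID
  variance; excluding singular fits would silently bias selection toward
  models that keep the random effect away from its boundary. Non-converged
  fits are excluded, with a log entry.
* **Coefficient p-values** are Wald z tests; with ~95 observations and ~57
  groups the difference from t-based approximations is small, and the
  choice is documented rather than hidden.
* **Variance decomposition.** Marginal and conditional R2 follow the
  Nakagawa variance-share construction with the fixed-effect predictor
  variance computed from the fitted design; the ID variance share
  `sigma2_alpha / (sigma2_alpha + sigma2_eps)` is reported as a percentage.
  Per-term semipartial R2 uses the Wald-F form
  `df1 F / (df1 F + df2)` with `df2 = n - k_fixed`, a simplification of
  adjusted-denominator methods, flagged as such; its CIs come from a
  parametric bootstrap.
* **Aliased columns.** Device type is fully confounded with year in the
  study design (monitor hardware changed between seasons); the fitter
  drops aliased columns and the bookkeeping follows the estimated
  coefficients.
* **Ties** in AICc are broken by fewer parameters, then label order, for
  determinism.

Year contrasts on the raw daily rates use a tie-corrected Kruskal-Wallis
rank-sum test implemented directly from the rank formula and verified
against the reference implementation to 1e-10. Where HRV and birthdate
co-occur in a confidence-set model, the HRV x birthdate variant is fitted
and compared by AICc (reactive and proactive mothers might occupy the
colony at different stages of the season); the comparison is reported, not
acted on.

## The synthetic colony: what it emulates and what it does not

`simulate_colony()` reproduces the study design: 57 mothers over 5 seasons,
each present in a year with probability 95/285 (expected 95 mother-year
rows, the study's size), two captures at days 3 and 14 post-partum,
birthdates near day 315, Polar devices in seasons 1–2 and Firstbeat after.
Latent individual resting HRV is lognormal (median 30 ms, sdlog 0.45) —
RMSSD is positive and right-skewed — with additive seasonal wobble whose SD
is set so that true repeatability is 0.63, the estimate the pipeline is
expected to recover. Mass metrics follow linear predictors whose
coefficients were scaled to the reported effect magnitudes (year effects
peaking in season 3, positive mass effects on both rates, a small positive
birthdate effect), and the residual SD of both daily rates is log-linear in
standardized latent HRV: `sd = exp(a + b z)`. This is the headline
mechanism — reactive mothers scatter more around the annual mean — injected
directly into the generative model so that recovery is a well-posed test.

Two generator choices deserve emphasis:

* **The residual-SD slope defaults to `b = 1`** (a 2.7-fold SD range per SD
  of HRV). The package's recovery study asks for reliable joint detection
  of the HRV coefficient in both deviance models at the study's size of ~95
  observations; a prospective power analysis showed that weaker slopes
  (e.g. 0.4) leave joint power near 35%, too low for a recovery property to
  be informative about correctness, while `b = 1` yields ~95% power per
  response with the false-positive rate at the nominal level when `b = 0`.
  The slope is a free parameter for any other use.
* **Conditional simulation of the latent variance** (`condition_latent`,
  default on): the latent HRV values of the repeat-measure mothers are
  rescaled so their sample variance equals its nominal value. With only
  ~25–30 multi-season individuals the realized variance ratio otherwise
  fluctuates so strongly (and the ratio is concave in the between-variance)
  that the *average realized* repeatability sits near 0.58 for a nominal
  0.63 — a property of sampling, not of the estimator, which tracks the
  realized ratio to within 0.002. Pinning the estimand makes "true R" exact
  in every replicate, which is what an estimator-recovery study needs.

The generator does **not** emulate: at-sea foraging, pup behaviour, weather
covariates, autocorrelated behaviour-state-dependent IBI noise (the
white/AR(1) choice is a stand-in, not a claim about seal physiology),
device-specific artefact signatures, or observation error in capture
masses. Passing recovery tests therefore demonstrates that the pipeline
recovers what the generative model encodes at the study's size — not that
the field data satisfy these structural assumptions.

## Problem sizes used in the packaged studies

The recovery studies shipped with the package use: 50 traces of 1500 s for
the RMSSD closed form; 10 traces of 3000 s at 1% missed + 1% extra beats
for the artefact round trip; 100 colonies with 200 bootstrap refits each
for repeatability recovery; and 100 signal plus 100 null colonies for the
heteroscedasticity study. These sizes keep Monte-Carlo error well below the
margins being tested (e.g. the SE of a 95% coverage estimate over 100
datasets is about 2 points).

## Known limitations

* Artefact correction is a documented local-median filter, not a
  re-implementation of any proprietary device software; thresholds are
  configurable but defaults were not tuned to any vendor's behaviour.
* The LRT p-value mixes no spatial or temporal autocorrelation structure;
  seasons are treated as exchangeable within individuals.
* Semipartial R2 uses the simplified Wald-F denominator; for small samples
  adjusted-df methods give somewhat wider intervals.
* `MTE` is a ratio of noisy rates; its expectation genuinely shifts with
  the residual variance of the denominator, so mean effects on MTE in
  heteroscedastic settings should be interpreted with care.
* The pipeline assumes each mother-year row is complete; partially missing
  capture data are dropped per response rather than imputed.
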