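---
title: "Methods: models, parameters, and design choices in noctivox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in noctivox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`noctivox` analyses nocturnal vocal activity of group-living diurnal
animals from passive acoustic monitoring (PAM) and synchronized
behavioral observation. This vignette documents the models the package
fits, the tunable parameters and their defaults, the numerical and design
choices made where the methodology leaves room, what the synthetic-data
generator does and does not emulate, and the known limitations.

## 1. The Acoustic Complexity Index

The acoustic stage reduces audio to a short-time power spectrogram
$P(f, t_i)$ (squared STFT magnitudes) and summarizes each fixed time
window by

$$\mathrm{ACI} \;=\; \sum_f \sum_i
  \frac{\lvert P(f,t_i) - P(f,t_{i-1})\rvert}{P(f,t_i) + P(f,t_{i-1})},$$

the summed relative intensity change between adjacent frames, per
frequency band. Each summand lies in $[0,1]$, so
$0 \le \mathrm{ACI} \le n_\mathrm{bands}\,(n_\mathrm{frames}-1)$, the
index is exactly zero for any time-constant spectrogram, and it is
invariant to multiplying all power values by a positive constant. These
three properties are enforced as tests.

Choices behind the implementation:

* **Zero denominator.** A frame pair with $P_i + P_{i-1} = 0$ (silence in
  that band) contributes 0. This keeps the index finite, makes silent
  bands inert, and makes ACI monotone in signal presence.
* **Normalization variant.** The per-pair normalization above is the
  package default. The classical soundscape-ecology variant — dividing
  each band's summed absolute differences by the band's *total* power in
  the window — is available via `aciValue(..., normalization = "total")`
  for comparison; the two differ whenever power varies within a window.
* **STFT parameters.** Frame 1024 samples, hop 512, Hann window by
  default; all configurable. A rectangular window is provided for
  analyses needing exact bin concentration of stationary tones. The frame
  count follows the standard convention
  $\lfloor (n - \mathrm{frame})/\mathrm{hop}\rfloor + 1$.
* **Windows.** ACI windows are consecutive and non-overlapping, 600 s by
  default. A trailing partial window is kept if it spans at least two
  frames and dropped otherwise, so no window ever has an undefined index;
  the whole-recording total is the sum over windows.
* **Hourly aggregation.** Windows are assigned to the clock hour of
  their *start* time, and the hourly ACI is the arithmetic mean of member
  windows. Mean (not sum) keeps hours with different numbers of windows
  comparable.
* **Band limiting.** `bandLimit()` keeps rows whose frequency band
  overlaps the requested interval (0–24 kHz by default, the focal
  species' vocal range), preserving order; an empty band is an error, not
  an empty object.

## 2. Vocal events and behavioral contexts

Raw call timestamps are merged into events by the rule that a gap
*strictly less than* 5 s continues the current event; a gap of exactly
5 s starts a new one. Merging is global by default because callers are
often unidentifiable at night; `perCaller = TRUE` applies the rule within
caller streams when identities exist. The merge is idempotent and
conserves calls (`sum(n_calls)` equals the input count); both properties
are tested against a brute-force gap-scan oracle.

Contexts collect behavior records within 10 s before the event start and
10 s after the event end. Both boundaries are **closed** — a record
exactly 10 s away is included — the maximal faithful reading of a
"within 10 s" rule, and ties at second resolution are therefore
included. Records falling strictly inside the event go to a separate
`during` phase that the hour × category summary excludes, since the
pre/post windows are what define an event's context. A record near two
events legitimately appears in both contexts (per-context counting).

The ethogram ships as a fixed dictionary of 21 behaviors in four
categories (aggression-, social-, sleep-related, other);
`classifyBehavior()` refuses unknown names rather than silently binning
them, so typos in field logs surface immediately.

Hourly counts run over a night window of 17:00–06:00 (end exclusive),
wrapping midnight; internally hours are indexed as hours-since-start,
externally reported as clock hours. Events outside the window are
dropped with a logged count.

## 3. Social metrics

* **DAI.** $D_{ab}/(D_a + D_b - D_{ab})$ per dyad; the matrix stage
  validates symmetry, zero diagonal, and the consistency bound
  $D_{ab} \le D_a + D_b$. A non-positive denominator is an error naming
  the dyad.
* **Eigenvector centrality** is computed by power iteration from a
  uniform start, with a spectral shift ($A + cI$, $c$ = the matrix
  maximum): the shift leaves eigenvectors unchanged but guarantees
  convergence on bipartite-like graphs (e.g. a star), where the
  unshifted iteration oscillates between the $\pm\lambda$ eigenspaces.
  Convergence tolerance $10^{-12}$ on the iterate, cap 10,000
  iterations, error with the residual on failure. On a disconnected
  association matrix each component's Perron vector is computed
  separately, scaled by its component's leading eigenvalue (so stronger
  components dominate), the combined vector max-normalized to 1, and a
  warning emitted. The weighted DAI matrix is used as is; binarizing
  before centrality is a documented alternative the package does not
  default to.
* **David's Scores** use raw dyadic win proportions, with
  non-interacting dyads contributing 0; the dyad-frequency-corrected
  variant is available behind `dyadCorrected = TRUE`. Scores always sum
  to zero (tested to $10^{-9}$ on random matrices), and reversing every
  outcome negates every score.
* **Rank tiers** come from 1-D K-means with $k = 3$, 50 restarts under a
  fixed seed (reproducibility), clusters labelled high/medium/low by
  descending mean. With 50 restarts on 1-D data the global optimum is
  found in practice; tests verify agreement with an exhaustive search
  over contiguous partitions. Fewer than $k$ distinct values is an
  error.
* **Kinship** counts direct relatives within the roster under the
  default relation set {parent, offspring, sibling sharing a known
  parent}; relations through individuals absent from the roster still
  link roster members. Cyclic pedigrees are rejected (Kahn's algorithm).

## 4. Temporal patterns

The peak/trough rule is descriptive: values strictly above Q3 are peaks,
strictly below Q1 troughs, boundary values normal. Quartiles use linear
interpolation of order statistics (`quantile()` type 7, the common
statistical-software default), which the test oracle reimplements by
hand. Because the rule is rank-based it is invariant under strictly
monotone transforms. It is not a test of bimodality, and the package does
not present it as one.

`validateAci()` always reports the Spearman coefficient and records the
Shapiro–Wilk gate outcome rather than switching estimators on the gate:
reporting both is more transparent than a data-dependent choice of
coefficient.

`hourSmoothTest()` fits `count ~ s(hour index, k = 8)` with a Poisson
family on per-night hourly counts, pooled across nights, the hour axis
wrapped to 0–12 from the evening start. The basis dimension 8 allows a
bimodal shape with room to spare while keeping the null well-behaved. A
caveat found while testing: if counts are overdispersed relative to the
Poisson family (e.g. a mixture of hourly rates), the smooth's score test
is anti-conservative; the package keeps the Poisson family as specified
and the test suite checks permutation behavior through explained
deviance, which is robust to this, rather than through nominal p-value
calibration.

## 5. Inferential models

**Count GLMM.** `count ~ rank + sex + age + centrality + relatives +
(1 | id)`, Poisson log link (`lme4::glmer`). Sex is coded with male as
reference so the female indicator carries the sex effect; continuous
predictors are z-scored by default. Coefficient magnitudes are only
comparable across data sets under a common scaling, so the recovery
simulations generate predictors already standardized and fit with
`standardize = FALSE` — one scaling applied to both generator and
fitter. With a single observation per individual the random intercept is
not estimable and the function degrades to a GLM with a warning; an
exposure offset (log hours recorded) is supported and leaves slopes
unchanged. Non-integer counts and optimizer non-convergence are errors,
not warnings. A VIF screen of the fixed-effect design is attached to
every fit; VIF is computed directly as $1/(1-R^2_j)$ from regressing
each design column on the rest, with perfect collinearity reported as
infinite plus a culprit-naming warning.

**Weather GAM.** Four candidates — main effects only, plus
temperature × humidity, plus temperature × precipitation, plus both —
with thin-plate smooths ($k = 8$) for the linear covariates, a cyclic
basis for wind direction (0° ≡ 360°, knots at the boundary), and
tensor-product `ti()` smooths (marginal $k = 5$) for the interactions,
fitted by REML. The candidate with the lowest AIC is pruned by backward
removal: while any smooth has $p \ge 0.05$, drop the largest-$p$ term
(ties broken by term order, which is fixed and documented) and refit,
possibly down to an intercept-only model. Basis dimensions shrink
automatically when a covariate has few unique values. Candidate fit
failures are skipped with a warning; all four failing is an error. The
returned table carries the per-term edf, reference df, F, and p, plus
the adjusted $R^2$, candidate AICs, and the removal trace.

A property of this screen worth stating plainly: with roughly nine
candidate smooths tested at a per-term level of 0.05, a well-calibrated
implementation retains *some* term on pure-noise input in roughly
$1 - 0.95^{9} \approx 35\%$ of data sets — backward selection controls
the per-term level, not the family-wise rate. The simulation suite
measures exactly this retention rate; a screen that reported near-zero
retention at this per-term level would be evidence of miscalibrated
p-values, not of a better procedure. Users wanting family-wise control
should tighten `alpha` accordingly.

**Friedman test.** Hours are blocks, behavior categories treatments,
ranked within blocks with average ranks for ties (`stats::friedman.test`
supplies the classical statistic with df $= k - 1$). Sleep-related
behaviors are excluded by default so the comparison covers the
aggression/social/other rhythms, includable by flag; a table with no
within-block variation returns statistic 0 and $p = 1$ rather than NaN.

## 6. The synthetic-data generator

The generator exists so every stage can be validated against known
ground truth. Its defaults describe the monitored system: a 17:00–06:00
night, 24 individuals, 48 kHz audio, a bimodal hourly call-rate profile
(elevated at 18:00–19:00 and 21:00–23:00, trough at 02:00–04:00, around
6 calls/h at the evening baseline and ~100 calls per night in total), and
count-model coefficients at field-realistic values
(intercept 7.748, rank −0.285, sex(female) −1.909, age −1.342,
centrality −2.163, relatives 0.249, on z-scored predictors, random
intercept s.d. 0.5). Every generator draws from a seed derived from the
config and restores the caller's RNG state; a fixed seed reproduces
outputs exactly.

* **Night audio.** Call times are an inhomogeneous Poisson process with
  the hourly profile. Each hour's soundscape is rendered on a short
  *duty-cycle segment* (60 s by default) that carries the hour's full
  call count — the desk-scale representation of an hour of activity —
  so hourly rate structure survives without synthesizing 13 h of 48 kHz
  audio. Calls are frequency-modulated harmonic stacks (fundamental
  520 Hz, 5 harmonics, 0.35 s, upward sweep plus vibrato) on Gaussian
  noise whose level rises with surface wind speed. The modulation is
  deliberate: a perfectly stationary tone barely moves the ACI, whereas
  a sweeping call crosses frequency bins and raises it, which is what
  couples planted call counts to measured ACI. Tests and the acceptance
  script run this generator at 8 kHz with 256/128 STFT frames and 10-s
  ACI windows — problem sizes chosen as the package's desk scale.
* **Behaviors** are placed within ±10 s of calls with hour-dependent
  category weights: aggression-heavy near 18:00, social-heavy near
  21:00–22:00, sleep rising late.
* **Social records** plant a linear hierarchy (logistic win probability
  in rank distance, steepness 0.75, ~8 bouts per dyad) and matriline
  clusters of 4 (proximity 600–1200 s within clusters vs 0–120 s
  between; one mother linked to the rest of each cluster).
* **Counts and attributes** run the GLMM forward at the configured
  coefficients.
* **Weather** is AR(1) per variable ($\phi = 0.8$; winter-night levels:
  temperature 5 ± 3 °C, humidity 75 ± 10 % clipped to [0, 100]), with
  wind speed and direction derived from the zonal/meridional components,
  rectified precipitation (mostly-dry hours), and a small rectified
  radiation term. `genCoupledAci()` adds planted partial effects — by
  default a unimodal response to meridional wind, a decline with wind
  speed, a periodic wind-direction effect peaking at 90° and 270°, and a
  cold-humid interaction — for GAM recovery tests. (Where the source
  analyses describe the wind-speed effect inconsistently, the generator
  follows the declining-ACI-at-high-wind description.)

What the generator does **not** emulate: realistic macaque call
acoustics, sound propagation and attenuation, non-target biophony,
recorder self-noise spectra, missing data, observer error in the logs,
or inter-night weather regimes. Passing tests therefore demonstrate that
the pipeline recovers structure it is pointed at under clean conditions
— correctness of the statistical machinery, not field-robustness of the
indices.

## 7. Problem sizes and limitations

The simulation suite uses 50 individuals × 30 nights and 100 replicates
for GLMM recovery and calibration, 400 h (recovery) / 160 h (null) × 100
replicates for the weather GAM, and 50 seeded nights for the end-to-end
soundscape run — sizes chosen to give stable rates on a single CPU in a
few minutes. Known limitations: the ACI responds to any fluctuating
sound, not only the focal species, so windy or rainy recordings inflate
it; the stepwise GAM screen controls the per-term, not family-wise,
error level (Section 5); Wald CIs in the GLMM rely on large-count
asymptotics; the quartile labelling is descriptive; and no interface
exists for call-type classification, which is outside the package's
scope.
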