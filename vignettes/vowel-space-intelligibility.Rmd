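---
title: "Vowel space metrics and intelligibility gain: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vowel space metrics and intelligibility gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vowelspace)
```

## The problem

Children with Down syndrome, and speakers with motor speech disorders
generally, often produce a compressed or centralised vowel space: vowel
targets crowd together in the (F1, F2) formant plane, reducing the acoustic
contrast listeners rely on. Clinicians would like acoustic summaries of that
space that (a) can be computed from a short, structured elicitation task and
(b) track functional outcomes such as word-level intelligibility scores.

`vowelspace` implements that analysis chain for a two-session (baseline /
post-intervention) design built on a ten-vowel /hVt/ word task (heat, hit,
het, hate, hat, hut, hoot, hood, hoed, hot), with three repetitions of each
word per session. The package consumes tabulated F1/F2 measurements (one row
per vowel token, midpoint formants extracted upstream, e.g. in Praat); audio
handling and formant tracking are out of scope by design.

## The three metrics

All geometry lives in the (F2, F1) plane in raw Hz. No Bark/mel/log
transform and no speaker normalisation is applied: the clinical change
scores this package models are expressed in Hz², and within-speaker change
scores are unaffected by any monotone per-speaker renormalisation that is
constant across sessions.

**AAVS (articulatory-acoustic vowel space).** The square root of the
generalised variance: with $S$ the $2\times 2$ sample covariance matrix
(denominator $n-1$) of the (F1, F2) values,
$\mathrm{AAVS} = \sqrt{\det S}$ (Hz²). It measures overall dispersion of
the vowel system and is zero exactly when the points are collinear.

**qVSA (quadrilateral vowel space area).** The shoelace area of the
quadrilateral through the mean positions of the four corner vowels,
traversed in the fixed perimeter order /i/ → /æ/ → /ɑ/ → /u/. This order
traces the vowel-chart perimeter; no traversal order is universally
standardised, so the package fixes one and additionally flags
self-intersecting quadrilaterals (possible in severely centralised speech)
rather than silently reporting a figure-eight "area".

**VSAhull (convex-hull vowel space area).** The area of the convex hull of
*all* tokens, pooled across vowels — the maximum articulatory reach.
The hull is computed with Andrew's monotone chain; vertices are reported
counter-clockwise with collinear boundary points excluded, which makes the
vertex list canonical and oracle comparisons in the test suite exact.

For any token set that contains the four corner vowels, qVSA computed from
per-vowel means can never exceed VSAhull computed from the tokens (means
are convex combinations of tokens); this containment is enforced as a
property test.

### Token-level versus mean-level AAVS

Two conventions circulate for AAVS inputs: the covariance of every token,
or the covariance of the ten per-vowel means. The two differ whenever
within-vowel scatter is nonzero — and they differ *even for identical
repetitions*, because duplicating every point rescales an $n-1$ covariance.
Rather than hide the choice, `session_metrics()` exposes it as
`mode = "tokens"` (default: dispersion of the whole production system,
sensitive to within-vowel consistency) or `mode = "means"` (dispersion of
vowel targets only), and records the mode in its output. qVSA always uses
means; VSAhull always uses tokens (a hull is duplicate-invariant, so the
distinction cannot matter for it).

## The intelligibility-gain model

Per speaker, change scores are post-minus-baseline differences of the three
metrics. The outcome model is ordinary least squares with intercept,

$$
\texttt{wcab\_ae\_gain} = \beta_0 + \beta_1\,\Delta\mathrm{AAVS} +
\beta_2\,\Delta\mathrm{qVSA} + \beta_3\,\Delta\mathrm{VSAhull} + \varepsilon,
$$

fitted by QR decomposition (`stats::lm`), with classical standard errors
$\hat\sigma^2 (X^\top X)^{-1}$, $\hat\sigma^2 = \mathrm{RSS}/(n-4)$, and
two-sided p-values from $t_{n-4}$. The gain score (a difference of
norm-referenced Growth Scale Values) is treated as a continuous response;
no ordinal machinery and no multiple-testing correction across the three
predictors is applied, matching standard linear-model reporting for this
design. An explicit normal-equations solve is kept in the test suite as an
independent oracle, never as the implementation.

Multicollinearity is quantified by the auxiliary-regression definition
$\mathrm{VIF}_j = 1/(1-R_j^2)$. On the packaged cohort records the VIFs are
about 4.2 (ΔAAVS), 1.6 (ΔqVSA) and 5.1 (ΔVSAhull) — ΔAAVS and ΔVSAhull
share substantial variance, which is worth knowing when interpreting their
individual coefficients at $n = 13$. Residual checks are numeric
counterparts of the usual visual diagnostics: Shapiro–Wilk on residuals,
studentised Breusch–Pagan, the slope of |residual| on fitted values, and
the four standard plot datasets as plain tables.

```{r fit}
fit <- fit_intelligibility_model(load_change_records())
fit
compute_vif(fit)
```

## Packaged data

Two small tables ship with the package and are pinned by checksum tests:
the per-speaker change scores and intelligibility gains for the 13-child
study cohort, and group-average formants for the ten vowels (the cohort at
baseline, plus reference values for typically developing 10–12-year-olds).
The group means and the figures derived from them are *carried as data*:
the underlying audio is not publicly available, so these values cannot be
recomputed, only transcribed, loaded, and plotted.

## The synthetic cohort generator

Because raw recordings are unavailable, validation rests on a generator
that emulates the study design's statistical structure. A token is

```
(f1, f2) = vowel target + speaker offset + session shift (post only) + token noise
```

and a speaker's gain is `β₀ + β·Δmetrics + N(0, outcome_sd)` with the
change scores computed from the speaker's own generated tokens.

Defaults are the study conditions wherever published numbers exist, and
are deliberately left alone otherwise:

* `n_speakers = 13`, `reps = 3`: the cohort size and task design.
* `vowel_targets`: the packaged baseline group means, so synthetic vowel
  spaces resemble the compressed configuration of the clinical group.
* `outcome_coefs = (-0.027, -0.00022, -0.00001, 0.00004)`: the published
  regression estimates.
* `outcome_sd = 4.05` gain units: the residual scale of the published fit.
* `session_shift = NULL` (zero): per-vowel shift magnitudes are shown in
  the source study only graphically, never as numbers, so nonzero defaults
  would be fabricated. Shift profiles are a configurable input instead.
* `speaker_sd = 50` Hz and `token_sd = 60` Hz are *illustrative*: no
  published within-vowel dispersion or between-speaker spread exists for
  this cohort. The values are plausible magnitudes for child vowel
  formants; every test that depends on dispersion states its own value.

Speaker offsets are a single (f1, f2) translation per speaker. This is a
modelling simplification chosen on purpose: all three metrics are
translation invariant, so speaker identity is cleanly separated from
vowel-space size, and between-speaker variation in the *change scores*
comes only from token noise and shifts. Randomness uses one stream per
cohort split into per-speaker substreams, so cohorts are bit-reproducible
and order-independent, and cohorts of different sizes share their leading
speakers.

What the generator does **not** emulate: formant-tracking errors (octave
jumps, merged formants), per-vowel anisotropic scatter unless configured,
age/sex covariates, session-to-session target drift unrelated to the
shift profile, and any dependence of gain noise on the acoustics. Passing
tests therefore demonstrate correctness of the *computations* under the
assumed data-generating process, not robustness of the clinical analysis
to real-world measurement pathology.

```{r simulate}
cfg <- cohort_config(n_speakers = 13, seed = 2026)
sim <- simulate_cohort(cfg)
fit_intelligibility_model(sim$gains)
```

## Numerical choices

* **AAVS determinant clamp.** $\det S$ is clamped to zero when it falls at
  or below $10^{-12}\, S_{11} S_{22}$, so numerically collinear inputs give
  an exact zero rather than a rounding-scale residue (Hz-scale inputs make
  the raw residue as large as ~10⁻⁴ Hz² after the square root).
* **Hull ties.** The monotone chain uses strict turn tests, so collinear
  boundary points are excluded and the vertex list is minimal; duplicated
  coordinates are legal everywhere and never affect hull geometry.
* **Self-intersection.** Polygon areas are always the absolute shoelace
  value; a crossing vertex sequence sets a warning flag instead of raising,
  because the flagged value is still useful for triage.
* **Confidence ellipses.** Axes come from the eigendecomposition of the
  sample covariance with semi-axis lengths $\sqrt{\lambda_i\,
  \chi^2_{2,\mathrm{cov}}}$ ($\approx 5.991$ at 95%); degenerate covariance
  raises rather than drawing a line-shaped "ellipse".
* **Degenerate inputs.** A metric that cannot be computed for a
  speaker-session (e.g. missing corner vowel) is reported as `NA` with a
  note, never as zero; downstream change-score construction excludes and
  reports such speakers.
* **Reading tables.** Structural faults (missing columns, duplicate token
  keys, non-numeric or non-positive formants, unknown session labels) are
  hard errors naming the row; phonetically suspicious values (F2 ≤ F1,
  frequencies outside 50–5000 Hz) are warning records, because mis-tracked
  formants are common in child speech and must stay visible to the analyst
  rather than being dropped or imputed.

## Validation scale and calibration

The test suite validates geometry against independent oracles (an O(n³)
supporting-line hull construction over 1,000 random instances of 3–60
points, and Monte-Carlo point-in-polygon area estimates at 10⁶ samples per
polygon over 100 random simple polygons), checks translation/scaling
invariances and the qVSA ≤ VSAhull containment over hundreds of randomized
token sets, and runs a parameter-recovery study: 1,000 replicates of
200-speaker cohorts generated at the published coefficients, refitted, and
summarised as per-coefficient bias, empirical SE, and 95%-CI coverage.
Coverage lands at 0.94–0.96 per coefficient, consistent with the nominal
level. Bias is within a couple of Monte-Carlo standard errors of zero;
note that a fixed-seed "within 2 SE per coefficient" reading of that check
has a ~17% familywise false-alarm probability across four coefficients
even for an exactly unbiased estimator, and the suite's frozen draw indeed
places one coefficient at 2.1 SE. The smaller calibration run in the
routine tests (200 replicates of 60-speaker cohorts) exists to keep the
default test pass fast while the full-scale study lives in the acceptance
suite.

## Known limitations

* The regression surface is the classical one: no mixed effects, no robust
  or Bayesian variants, and no causal interpretation — with 13 speakers and
  correlated predictors the model is descriptive.
* qVSA's fixed corner traversal can self-intersect for severely
  centralised speakers; the flag is reported but no re-ordering is
  attempted.
* The package takes formant tables as ground truth; nothing guards against
  systematic extraction error upstream.
* The VIFs on the packaged cohort records (max ≈ 5.1) exceed the
  conventional comfort threshold of 2 that is sometimes quoted for this
  design; users should weigh the individual ΔAAVS and ΔVSAhull
  coefficients accordingly.
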