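---
title: "Methods: landscape forest cover, extinction thresholds and tree communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape forest cover, extinction thresholds and tree communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragthresh)
```

## The problem

In fragmented tropical forest landscapes, the amount of native forest
remaining around a site ("forest cover amount", in percent of a circular
buffer) is a leading predictor of how many tree species and individuals
persist inside forest remnants. Two questions recur in this literature:
at which spatial scale (buffer radius) does forest cover act, and does the
community decline smoothly with forest loss or collapse abruptly below an
*extinction threshold* — a cover value at which richness or abundance
drops rapidly?

`fragthresh` implements the full analysis chain for a *patch-landscape*
study design: responses (species richness and abundance — overall, per
focal family, and per functional-trait group) are measured inside ~20
focal sites, while the predictor is percent forest cover in buffers of
500, 1000, 1500 and 2000 m radius (landscape areas of about 78.5, 314,
706.9 and 1257 ha).

## The analysis pipeline

`run_pipeline()` executes the stages in order; each is also exported on
its own.

### 1. Scale of effect

For each response, the Spearman rank correlation with cover is computed
at every radius (`select_scale()`); the radius with the largest
`|rho|` wins. Absolute correlation is used because declining and
increasing responses are equally informative; ties break toward the
smaller radius (the most local mechanism). Both choices are deliberate
design decisions — the underlying field practice varies — and
`use_abs` is an argument. The pipeline picks a single working radius by
majority vote across responses, which mirrors how multi-response studies
settle on one scale.

### 2. Spatial-dependence screening

Site-level responses may be spatially autocorrelated, which invalidates
the iid likelihoods of stage 3. `mc_envelope_test()` computes the binned
empirical semivariogram

$$\gamma(h) = \frac{1}{2 N_h} \sum_{(i,j): d_{ij} \in h} (z_i - z_j)^2$$

with 6 equal-width lag bins up to half the maximum intersite distance,
and compares it to a pointwise envelope built from `n_sim = 1000` random
permutations of the values across site locations (a distribution-free
surrogate for complete spatial randomness; permutation preserves the
value multiset exactly). A response is *flagged* when any bin leaves the
two-sided `alpha = 0.05` envelope.

The any-bin rule is liberal: with six bins and a 5% pointwise envelope
the per-response false-flag rate is about 29% (measured over 500
replicates of iid values in this package's own calibration test). This
is common field practice but worth knowing: in a catalogue of 14
responses, three to four flags are expected even without any spatial
structure, so a small number of flagged responses is not by itself
evidence of spatial pattern. A stricter `rule = "consecutive2"` (two
adjacent bins outside) is available.

At 20 sites the test's power is also modest. Against a pure exponential
Gaussian field with range several times the bin width, the flag rate is
roughly 80-90%, not higher; once a strong cover-driven trend and
sampling noise are superimposed (as in realistic community data), power
drops well below that. Screening results at this sample size should be
read as a routing heuristic, not a hypothesis test.

### 3. Four-model selection and thresholds

For each response, four mean functions of cover $x$ are fitted by
maximum likelihood (`fit_candidate()` / `fit_cover_models()`):

* null: $\mu = c$
* linear: $\mu = \beta_0 + \beta_1 x$
* power law: $\mu = a x^b$ (no intercept; $x > 0$)
* four-parameter logistic:
  $\mu = L + (U - L) / (1 + e^{(x_0 - x)/s})$, with lower and upper
  asymptotes $L, U$, inflection $x_0$ and scale $s > 0$; $\mu(x_0) = (L+U)/2$.

The default error family is Gaussian on the response scale (a Poisson
likelihood is selectable for counts). During optimization $\sigma$ is
concentrated out analytically ($\hat\sigma^2$ = mean squared residual),
with analytic gradients, bounded L-BFGS-B, and data-driven starts (null:
mean; linear: least squares; power: log–log regression; logistic:
asymptotes at the response range, inflection at the median cover) plus
jittered restarts — 20 for the logistic, whose likelihood is multimodal
at $n = 20$. The parameter count $k$ used by AICc *includes* $\sigma$
(null 2, linear 3, power 3, logistic 5); at $n = 20$ this materially
penalizes the logistic, so the convention is stated prominently.

A fit is *convergent* only if the optimizer succeeded (or the projected
gradient is numerically zero — L-BFGS-B occasionally aborts its line
search when started at the optimum), no estimate sits on a bound, and
the Hessian at the optimum is finite and positive definite (skipped for
exactly interpolating fits, where the concentrated surface degenerates).
Non-convergent fits are excluded from ranking — on strongly linear data
the logistic is regularly excluded this way, which is the intended
behaviour.

Convergent fits are ranked by the small-sample criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$; the *parsimonious set*
is all models with $\Delta\mathrm{AICc} \le 2$, with Akaike weights
reported. When the null model is in the set, the response is reported as
no better explained than by chance.

When the logistic is parsimonious, the extinction threshold is its
inflection $x_0$ with a profile-likelihood 95% CI
(`estimate_threshold()`): the remaining parameters are re-optimized on a
grid of fixed $x_0$ and the $\chi^2_1$ cutoff is inverted by
root-finding, falling back to a Wald interval if profiling fails. Bounds
are clipped to [0, 100] percent cover. In this package's coverage
experiment (200 replicates, $n = 20$, true $x_0 = 29$, residual sd 3),
the profile CI covers the truth 94% of the time.

### 4. Spatial linear models

Flagged responses are refitted as spatial linear models
(`fit_spatial_linear()`): the same null/linear/power means with a
Gaussian error whose covariance is exponential in distance,
$\Sigma_{ij} = \tau^2 \mathbf{1}[i=j] + \mathrm{sill}\cdot e^{-d_{ij}/\phi}$,
all parameters estimated jointly by ML (not REML, so AICc is comparable
across mean structures; the three covariance parameters count toward
$k$). The logistic is excluded on this path — it does not adjust
reliably under the spatial likelihood — so flagged responses are
compared over exactly three models. "Spatial linear model" is read here
as variogram-style GLS; a spatial-error lag model is a different
(untaken) reading.

### 5. Forest cover vs edge distance

The second covariate is the mean distance from the survey plots to the
nearest forest edge. For each response, four candidates — null,
cover-only, edge-only, cover+edge — are fitted on natural-log-transformed
predictors (responses are never transformed) and ranked by AICc
(`build_and_rank()`). The engine follows the earlier stages
(`dispatch_engine()`): spatially flagged responses use the spatial GLS
engine; responses whose best cover model was non-linear use a penalized
cubic-spline smoother (cubic regression basis, GCV-selected penalty, via
`mgcv`); otherwise ordinary Gaussian GLM. The summary table reports the
best model's coefficient signs with significance stars (Wald tests for
GLM/GLS, the smooth-term approximate test for splines) and a dash when
the null model is parsimonious; stars are labels only — selection is by
AICc.

### 6. Ordination

Community composition is summarized by correspondence analysis
(`correspondence_analysis()`): SVD of the standardized residual table,
eigenvalues $\lambda_k$ = squared singular values, variance explained
$\lambda_k / \sum \lambda$. Detrending (`detrend_axis()`) removes the
arch artefact by centering axis-2 site scores within 26 equal-width
segments of axis 1 (Hill's detrending-by-segments; undersized segments
merge). No nonlinear rescaling is performed, so axis-1 *variance
fractions are not comparable to DECORANA output*, and no axis
significance test is attached.

## The synthetic-data generator

No field data ship with the package; `simulate_dataset()` generates
communities with the statistical structure the pipeline assumes, at the
scale of the emulated survey:

* 20 sites in a 60 × 60 km region, at least 1 km apart; percent cover at
  the working radius stratified-uniform over 3–93% so the gradient is
  always spanned; cover at the other radii correlated 0.9 with it
  (configurable; 1 gives identical covers, 0 independent ones).
* A 512-species pool whose focal families get exactly the emulated
  survey's counts (Myrtaceae 84, Fabaceae 65, Rubiaceae 32, Sapotaceae
  32, Lauraceae 25) under largest-remainder rounding; remaining species
  are pooled in a single "Other" family rather than 48 minor families.
* Trait completeness mirroring a real survey: regeneration known for
  ~90% of species, dispersal for ~96%, seed diameter for ~66% of
  biotic-dispersed species (lognormal, median 0.8 cm, giving ~25%
  large-seeded); seed size is only defined for zoochoric species.
* Overall per-site targets: richness 38 + 0.4·cover (sd 4), abundance
  72 + 0.5·cover (sd 6). These keep abundance within the emulated 60–129
  range for over 90% of sites and give means near 96 individuals and 57
  species per site. Targets are met exactly when noise is off: each site
  receives exactly its target richness in species (weighted sampling
  without replacement), one individual each, and the remainder
  multinomially.
* Species sampling weights are lognormal rank-abundance weights times
  per-group cover multipliers (`default_group_effects()`): Lauraceae
  collapses logistically at 29% cover, Myrtaceae declines linearly,
  Sapotaceae and the shade-tolerant/biotic/small-seeded groups follow
  power laws, and the complementary groups are cover-indifferent.
* Optionally, a Gaussian random field with exponential covariance
  (simulated exactly by Cholesky factorization, adequate up to a few
  hundred sites) is added to the abundance targets, so spatial structure
  appears in abundance-type responses.

Everything is driven by a single integer seed; a fixed seed gives
bit-identical output, and the three tables round-trip exactly through
their CSV forms.

What the generator does **not** emulate: within-site plot structure (the
five field plots collapse into one site sample), family-linked trait
syndromes (traits are drawn independently of family), raster forest-cover
maps, and observation error in cover estimation. Consequently, passing
tests demonstrate that the *analysis machinery* behaves correctly under
the assumed statistical structure — not that real surveys satisfy that
structure.

## Numerical and design choices

* Seed-size boundary closed on the small side: diameter ≤ 1.2 cm is
  "small".
* Species with an unknown value for a trait are excluded from that
  trait's subsets but kept in overall responses.
* CSV dialect: comma separator, "." decimal, UTF-8, mandatory header.
* Logistic parameterization uses the increasing-with-cover convention
  ($s > 0$); decreasing responses are represented by $U < L$.
* The power law is $a x^b$ without intercept (with $b = 1$ it matches a
  through-origin line exactly in likelihood).
* Optimizer bounds: logistic asymptotes within the response range ± 2
  ranges, inflection within the observed cover range, scale within
  [10⁻⁴, 4] cover ranges; estimates touching a bound mark the fit
  non-convergent.
* GLS covariance parameters are optimized on the log scale with the mean
  profiled out where it is linear; a tiny ridge (10⁻⁸ of the mean
  diagonal) guards Cholesky factorizations.
* Degenerate inputs: constant predictors yield non-convergent (not
  crashing) fits for non-null models; all-zero ordination rows/columns
  are dropped with a warning; constant responses give an `NA` Spearman
  correlation with a warning.

## Problem sizes used by the test suite

The simulation experiments run at the emulated survey scale of 20 sites:
inflection-recovery coverage uses 200 replicates, null-model retention
500, generating-model recovery 200, scale-of-effect recovery 100, and
the envelope power and calibration experiments 200 and 500 replicates
(499 permutations each). The full pipeline (20 sites, 24 responses,
1000-permutation screening) runs in well under a minute on one CPU, and
two runs from the same seed write byte-identical reports.

## Known limitations

* The Monte-Carlo envelope at 20 sites has both a high baseline flag
  rate under the any-bin rule and limited power (see stage 2); its
  output routes responses between engines rather than establishing
  spatial dependence. The package's own power experiment against
  long-range Gaussian fields measures roughly 80-85% detection, short
  of the ~95% one might hope for; more sites, more bins, or a stricter
  decision rule change this, but those are study-design choices.
* Profile CIs for the inflection can hit the [0, 100] clip in weakly
  informative samples; the `method` tag records profile vs Wald.
* The spline engine is a single-smooth Gaussian stand-in for a full GAM;
  tensor interactions and non-Gaussian families are out of scope.
* Correspondence analysis here is not DECORANA: no nonlinear rescaling,
  so published DCA variance figures are not directly comparable.
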