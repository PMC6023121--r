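---
title: "Methods: PLS gradient analysis of riparian plant functional types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS gradient analysis of riparian plant functional types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riparianPLS)
```

## The scientific setting

Permanent headwater streams are detritus-based ecosystems: their food webs
run on leaf litter from the riparian strip. The palatability of that litter
differs sharply between plant functional types (PFTs) — giant graminoids
(GG), evergreen shrubs and trees (ES, ET), deciduous shrubs and trees
(DS, DT) — because the types differ in specific leaf area, toughness,
nitrogen, C:N, lignin and silicon. A space-for-time gradient design asks
how the abundance (% cover) and Simpson diversity (1 − D) of each PFT
respond to climate, riparian soil and stream-physical predictors across a
broad aridity gradient, and reads the spatial answer as a forecast of
temporal change under warming and drying.

This package implements that full inference chain, with a synthetic study
generator in place of the (undeposited) field measurements, so that every
stage can be validated by oracle equivalence and parameter recovery rather
than by re-reading published tables.

## The PLS engine

The core statistic is partial least squares regression. Predictors and
responses are centred and scaled to unit variance (sample SD, n − 1;
declared in all output metadata). Per component, NIPALS iterates
`w ∝ X'u`, `t = Xw`, `c = Y't/t't`, `u = Yc/c'c`; we compute its fixed
point exactly — `w` is the dominant left singular vector of the
cross-covariance `X'Y`, obtained from the small `m × m` eigenproblem of
`Y'XX'Y` — which removes any dependence on an iteration tolerance and is
robust where power iteration converges slowly (near-tied eigenvalues under
weak signal). `X` is deflated by `t p'` (no Y-deflation; for a univariate
response this is the classical PLS1). Scores are mutually orthogonal and
weights unit-norm by construction, and both properties are asserted in the
test suite after every fit.

Standardized coefficients are `B = W (P'W)⁻¹ C'`; with both blocks scaled,
these are directly comparable across predictors, and for a single
predictor the coefficient equals the Pearson correlation.

**Cross-validation.** Predictive power is leave-one-out `Q²`. For each
held-out site the entire model — including the centring/scaling of `X` and
`Y` — is refit on the remaining sites, so no scaling information leaks into
the fold. Two conventions coexist and both are reported:

* per-component `Q²_a = 1 − PRESS_a / RESS_{a−1}` (with `RESS_0` the total
  sum of squares) drives the component-entry rule;
* cumulative `Q²_A = 1 − PRESS_A / SS_tot` is the reported predictive
  power (the convention used when a single "Q²" is quoted).

Components are admitted while their per-component Q² exceeds 0.097 (the
conventional 5% significance limit for this sample size), and among the
admissible counts the one maximising cumulative Q² is kept ("maximum Q²"
rule). A selection of zero components marks a non-significant model; such
models are still tabulated with one component and a significance flag,
which is how single-component models with negative Q² conventionally
appear in summary tables.

PRESS, RESS and R²(Y) are pooled on the raw response scale. Responses
within one model share units (arcsine radians for covers, 1 − D for
diversities), so raw-scale pooling is well defined; the per-component
Y-variance weights used inside VIP are taken on the unit-variance basis,
which is the standard VIP formulation. VIP is
`VIP_j = sqrt(p · Σ_a SSY_a w²_aj / Σ_a SSY_a)`; mean VIP² = 1 exactly, so
VIP > 1 is "above average importance".

## The modelling protocol

1. **Transforms.** Percent covers are arcsine-square-root transformed
   (covers only, never diversities). Leaf traits are natural-log
   transformed before ANOVA and clustering; F statistics and Tukey results
   are invariant to the log base.
2. **Pruning.** Within each predictor block, while any pair has
   |Pearson r| > 0.85, the member with the lower preliminary VIP (from a
   one-component PLS on the pooled multivariate response set) is dropped;
   blocks still wider than 8 variables then lose their lowest-VIP members.
   Every removal is logged with its reason.
3. **Block comparison.** Multivariate PLS models for the cover set and the
   diversity set across the seven block combinations (C, S, P and their
   unions), each with component selection and a leave-N-out summary.
4. **Univariate models.** For the twelve responses (cover and diversity of
   five PFTs, total canopy cover, total diversity): one-component VIP
   prescreen on the pooled pruned table (keep VIP > 0.9, cap at the 15
   highest), then leave-N-out assessment; the VIP report lists only
   predictors with fold-mean VIP > 1, in descending order.
5. **Leave-N-out.** Sites are randomly split into 5 near-equal groups
   (7/7/7/7/6 at n = 34); each fold refits scaling and component count on
   its training subsample. Fold Q² is, by default, the internal
   leave-one-out Q² of the training subsample; evaluating each fold on its
   held-out group instead is available via `lno_eval = "holdout"`. The
   default reflects how tabulated per-fold Q² values behave in this
   literature (five internally cross-validated sub-models); the choice is
   configurable because the original protocol wording is ambiguous.
   Predictor selection (pruning, prescreening) is frozen from the
   full-data model and reused in folds — refitting selection per fold
   would change the meaning of the fold-wise VIP mean/SD summaries.

Tunable parameters, with defaults and units:

| parameter | default | meaning |
|---|---|---|
| `r_threshold` | 0.85 | pruning correlation cut (dimensionless) |
| `target_width` | 8 | max variables per block |
| `vip_cut`, `max_vars` | 0.9, 15 | univariate prescreen |
| `q2_threshold` | 0.097 | component entry (Q² units) |
| `n_groups` | 5 | leave-N-out folds (~20% of sites each) |
| `ncomp_max` | 10 | component search ceiling |
| `noise_sd` | 0.3 | generator residual SD (arcsine radians) |

## The synthetic study generator

The generator emulates the statistical structure the analysis assumes, not
the geography that produced it. One latent "aridity" axis per landscape
drives precipitation (−), temperature (+), days of rain (−) and, through a
configurable coupling, the soil variables that track aridification (EC,
pH, exchangeable sodium, base saturation up; organic carbon down).
Potential evapotranspiration loads against precipitation (latent
r ≈ −0.93), so PET is strongly redundant with the UNEP ratio PP/PET — the
collinearity that motivates the pruning stage. The aridity indices (PP/PET,
de Martonne, Emberger Q2) and C:N are computed from the sampled columns,
never sampled.

**Marginals.** Each sampled variable is a standard-normal score (loading ×
aridity + independent residual) pushed through a calibrated marginal by the
inverse-CDF transform, which preserves the latent rank structure.
Near-symmetric variables use a range-truncated normal whose underlying
parameters are solved (Nelder–Mead on closed-form truncated moments) so the
*truncated* distribution hits the target mean and SD. Several bounded soil
and physical variables are more dispersed than any truncated normal can be
inside their observed range (e.g. organic carbon: target SD 1.79 on
[0.10, 5.41], while the uniform limit is 1.53); these use a range-scaled
beta with exactly moment-matched shape parameters. The test suite verifies
all 25 marginals at n = 2000 to within 5% (means) and 10% (SDs).

**Responses.** Covers are built where the analysis assumes linearity — the
arcsine-sqrt scale: `θ = θ0 + X_std β + ε`, clipped to [0, π/2], then
back-transformed to percent. Per-PFT Simpson diversity comes from a
symmetric Dirichlet species-abundance draw whose concentration (hence
evenness) increases with the same linear predictor, keeping diversity
mechanistically tied to abundance. Total canopy cover is the
complement-product of the three woody covers; total diversity is Simpson
1 − D over the pooled cover-weighted species abundances.

**Effects.** The default effect matrix encodes only the sign structure the
field system reports — aridity (via PP/PET, temperature, and the coupled
soil variables) favours giant graminoids and disfavours deciduous trees;
precipitation, Emberger's Q2 and mild winters favour evergreens; altitude
favours deciduous trees; deciduous-shrub cover and total diversity carry
only trace signal (the two conventionally non-significant rows). Effect
*magnitudes* are free parameters (no effect sizes are published for the
field system); the defaults (|β| between 0.15 and 0.45, residual SD 0.3)
were chosen once to give the downstream models Q² values in the published
range and are not revisited per test.

**Leaf traits.** Species-level lognormal draws (SD 0.18 on the log scale)
around per-PFT medians ordered as the trait syndromes require: deciduous
SLA and %N above evergreen, deciduous toughness and C:N below, GG silicon
far above and lignin below everyone. The 102-leaves-per-species measurement
hierarchy is collapsed to species means; leaf-level nesting is out of
scope. Species counts default to 3/6/5/3/15 (GG/ES/ET/DS/DT; 32 species).

**What the generator does not emulate** — and hence what green tests do
not certify about real data: spatial autocorrelation and raster structure,
hydrological disturbance regimes, species-level biogeography, non-Gaussian
residual dependence between responses beyond the shared latent axis, and
measurement error in the trait protocol. Parameter-recovery results say
the *method* works under its own assumptions, not that the assumptions
hold in the field.

## Numerical and design choices

* **Exact NIPALS fixed point** (see above); deterministic sign convention
  (largest-|w| element positive). Degenerate input — an X residual with no
  covariance left — raises an error naming the component.
* **Tukey for unequal n** is Tukey–Kramer (harmonic pairwise n) on the
  studentized range distribution; the two-group case collapses to the
  pooled t-test (q = √2·|t|), which the tests assert analytically.
  Compact letters use the interval method on groups ordered by mean.
* **ANOVA** is the classical SS decomposition; the all-constant degenerate
  case is reported as F = 0, p = 1.
* **Elbow** is operationalised as the maximum second difference of the
  within-cluster SS over K = 2..5 (interior K only); K-means uses 50
  seeded restarts, ties broken by lowest WSS. All-identical input is
  reported as degenerate rather than forced to a K.
* **Aridity-index identifiability.** The four moisture indices (PP,
  PP/PET, de Martonne, Q2) are mutually r > 0.94 by construction — the
  published coefficient of variation of PET is small, so any generator
  matching the published marginals has r(PP, PP/PET) ≈ 0.97. The pruning
  rule therefore collapses them to a single survivor whose identity is
  decided by sampling noise at n = 34. Tests treat the identity of the
  survivor as a frequency property, not a constant.
* **Seeds.** Every stochastic step (generator, LNO partition, K-means
  restarts) flows from one explicit seed; reports embed seed, partition
  and configuration, and the byte-identity of repeated runs is a test.

## Problem sizes

The shipped tests and the acceptance script run at the study scale:
n = 34 sites, 24–29 predictors, 12 responses, 32 species; calibration
checks use n = 2000 sites; replicate-based properties use 10–100
replicates (null calibration 50–100, attribution 20–50, trait clustering
50 seeds). The full pipeline on one 34-site dataset takes ~15 s on one
CPU; the complete test suite a few minutes.

## Known limitations

* Q² conventions differ across software; results are comparable across
  conventions only via the cumulative form, which is why both are stored.
* The correlative design supports attribution ("which block predicts
  best"), not causal inference; the package deliberately implements
  nothing beyond the protocol's scope.
* With five LNO folds the mode/range of N and SDs of Q² are coarse
  summaries; they are reported exactly as such, not as confidence
  intervals.
* The Domin–Krajina midpoint table is one published variant; it is a
  replaceable argument because variants differ, and conversions are
  documented in the output metadata.
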