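---
title: "Composite bone scores: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite bone scores: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonescore)
```

## The problem

Micro-CT phenotyping of mouse long bones produces panels of correlated
variables per compartment: five trabecular measures (BMD, BV/TV, Tb.Th,
Tb.Sp, Tb.N) and up to ten cortical measures (areas, thickness, perimeters,
principal second moments of area, tissue mineral density). Comparing
cohorts raises two distinct difficulties:

1. **Harmonization.** Different colonies, ages, scanners and analysis
   pipelines shift every variable's location and scale, so raw values from
   two mouse models cannot be pooled directly.
2. **Multivariateness.** Trisomy and related genetic manipulations rarely
   move a single variable; they move many correlated variables a little.
   Testing each variable separately and correcting for multiplicity
   dilutes exactly the signal one is looking for.

`bonescore` addresses both with a two-step construction: within-model
z-standardization followed by a first-principal-component composite score,
plus the factorial statistics, bend-test extraction and cross-section
geometry that surround such an analysis.

## The model

### Within-model standardization

Each variable is standardized per *stratum* — by default (mouse model,
sex, age) — using the mean and sample SD (denominator `n - 1`) over **all**
animals of that model in the stratum, pooling both genotypes:

$$z_{iv} = \frac{x_{iv} - \bar{x}_v^{(s)}}{\mathrm{sd}_v^{(s)}}.$$

Pooling genotypes is essential: it removes background-strain and
methodology offsets while leaving the euploid-trisomic contrast intact.
A direct consequence is that each model's marginal mean of every z-score
(and hence of any linear composite) is exactly zero, so in a balanced
design the mouse-model main effect on composite scores has a sum of
squares of zero by construction. This is the mechanism behind null model
effects in harmonized cross-model comparisons, and it is asserted to
`1e-8` in the test suite.

Animals missing any variable of a compartment are excluded from that
compartment's standardization and PCA (complete-case per compartment); no
imputation is performed. When cohorts were measured on incompatible
scales for one variable (e.g. areal versus volumetric density), that
variable can simply be left out of the `variables` argument for the run.

### PC1 composite scores

The pooled z-scores of one compartment are decomposed by PCA
(`pc_composite()`, built on the sample covariance matrix of the
standardized values; a correlation-matrix switch exists but the two nearly
coincide for z-score inputs). Only the first component is ever scored:

$$\mathrm{score}_i = \sum_v \ell_v \, z_{iv},$$

with $\ell$ the unit-norm PC1 loading vector. Components beyond PC1 are
reported in diagnostics (`summary()`, `plot()`) but never enter a score.
Because an eigenvector is defined only up to sign, the component is
oriented by an anchor variable forced positive — BV/TV for trabecular and
Ct.Ar for cortical scores — so a *lower* composite score always reads as
*less or weaker bone*. On trabecular panels the oriented PC1 loads
positively on BMD, BV/TV, Tb.Th and Tb.N and negatively on Tb.Sp, because
trabecular separation is inversely correlated with the rest and higher
separation is the deficit.

PCA centering is applied explicitly even though pooled z-means are zero
stratum-wise; with unbalanced groups the pooled column means are still
exactly zero (each stratum contributes mean zero), so centering is a
numerical formality, and scores computed as plain inner products agree
with the centered projection to floating tolerance.

Scorers are fit separately per sex and per comparison set and never
reused across strata; `run_pipeline()` enforces this.

### Factorial statistics

The statistics layer mirrors standard practice for unbalanced factorial
phenotyping designs:

* `gate_assumptions()` — Shapiro-Wilk at $\alpha = 0.05$ on the full
  model's residuals (a per-cell switch exists); on failure and if all
  values are positive, natural-log transform and retest. Levene's test
  (center = mean) flags heteroscedasticity. The log base does not affect
  any test decision; the natural log is used.
* `factorial_anova()` — full-interaction fixed-effects model with
  sum-to-zero coding and Type III (each-term-last) sums of squares,
  appropriate when group sizes differ; on balanced designs Type III
  coincides with sequential sums of squares, which the tests assert.
* `welch_reassess()` — when both Levene and a term are significant, a
  one-way Welch F across the term's marginal groups is run as a
  side-check; if Welch disagrees the term is reported non-significant.
  The one-way marginal reading is a deliberate choice: a heteroscedastic
  factorial model is not defined here, and the reassessment is a check,
  not a replacement.
* `sidak_pairwise()` — comparisons of one factor's levels within slices
  of the others, using the pooled residual mean square; the family size
  `m` is the number of comparisons actually performed in the stated
  slicing, recorded in the output.
* `bonferroni_contrasts()` — cell-mean contrasts with
  $p_{adj} = \min(1, m\,p)$.
* `chi_square_gof()`, `groupmean_correlation()` — transmission-ratio
  tests and group-average correlation with two-tailed t significance on
  `k - 2` degrees of freedom.

### Bend mechanics

`summarize_mechanics()` extracts nine whole-bone and seven tissue-level
properties from a three-point-bend force-displacement trace:

* Preload trimming at 0.2 N with linear interpolation of the crossing;
  the curve is re-zeroed there.
* Beam equations $\sigma = FLc/4I$ and $\varepsilon = 6cd/L^2$, with $c$
  the centroid-to-surface distance along the loading direction and $I$
  the second moment about the bending axis ($I_{min}$ for
  anterior-posterior loading).
* Stiffness from a deterministic window search: contiguous windows of at
  least 15% of the pre-ultimate samples, forces within 10-90% of
  ultimate, maximizing regression $R^2$. Exact ties are broken toward
  the **earlier start**, then the larger window: on an ideal bilinear
  curve both segments are perfectly linear, and the earlier-start rule is
  what guarantees the elastic segment is chosen. Flat-force windows are
  scored $R^2 = 0$ (the 0/0 convention would otherwise let a plateau
  "win"). A best window below $R^2 = 0.9$ triggers a low-linearity
  warning but is still used.
* Yield by the 0.2% offset method (2000 microstrain) on the stress-strain
  curve, using the elastic stress-strain slope implied by the fitted
  stiffness ($kL^3/24I$ — note this is twice the beam modulus
  $kL^3/48I$, a standard consequence of the midspan strain formula);
  intersections are located by linear interpolation, and the same
  interpolation fraction defines yield on the force-displacement curve.
  A curve that never crosses the offset line is flagged `no_yield` with
  yield placed at the ultimate point.
* Ultimate at the first force maximum; failure at the first post-ultimate
  drop below 10% of ultimate (a configurable operational rule — "where
  the bone broke" needs one); traces that never drop are flagged
  `no_failure` and excluded, mirroring specimens that reach maximum
  machine displacement intact.
* Works are trapezoidal areas under force-displacement (mJ), split at
  yield so work-to-yield plus post-yield work equals total work exactly;
  resilience and toughness are the stress-strain areas to yield and to
  failure (MPa).

One consequence of preload re-zeroing worth knowing: the offset line is
anchored at the re-zeroed origin while the curve starts at the preload
force, so on an ideal curve the yield displacement equals the elastic
rise plus the offset displacement plus the small preload-equivalent
displacement ($0.2/k$). The tests carry this term in their closed forms.

### Cortical geometry from binary masks

`segment_compartments()` labels cortex, marrow and outside via connected
components (4-connectivity), requiring exactly one cortex component
enclosing exactly one cavity — a cortical break that lets the cavity leak
to the border is a topology error, not a silent misestimate. Areas are
pixel counts times pixel area (`Ct.Ar + Ma.Ar = Tt.Ar` exactly); the
centroid is the total-section pixel average (a cortex-only switch
exists). Radial profiles cast 720 rays (0.5-degree steps) from the
centroid and find the endocortical and periosteal crossings of the
bilinearly interpolated cortex indicator at the 0.5 level, giving
sub-pixel radii; cortical thickness is the mean periosteal-minus-
endocortical radius over angles — consistent with the radial-profile
machinery rather than a 3D sphere-fitting definition, and validated on
annuli where both coincide. Group-average cross-sections
(`average_profile()`) are per-angle means across animals, one profile per
animal first.

Perimeters are marching-squares contour lengths at the 0.5 level after a
3x3 box smoothing of the binary indicator. The smoothing matters: raw
binary marching squares overestimates a circle's perimeter by about 6%
(measured +5.8% at a 50-pixel radius; naive pixel-edge counting is far
worse at ~27%), while the smoothed contour is within ~0.7% — inside the
2% closed-form tolerance the geometry tests enforce. Principal second
moments come from pixel summation about the cortex centroid including
the per-pixel self moment $p^4/12$, with $I_{max}/I_{min}$ the inertia
tensor eigenvalues.

## The synthetic cohort generator

`generate_cohort()` draws each factorial cell's variable panel from a
multivariate normal with mean `baseline + summed effects` and covariance
$D R D$ ($D$ the diagonal of per-variable SDs, $R$ the compartment
correlation matrix). Design choices, all fixed once:

* **Effects are additive in SD units** on the raw scale, which makes
  recovery targets analytic after standardization. One caveat the tests
  encode: pooled standardization inflates the stratum SD when the groups
  truly differ, so a $\delta$-SD separation between balanced groups
  appears as $\delta/\sqrt{1 + \delta^2/4}$ in z units.
* **Default correlations are assumptions, not estimates** — no variable
  correlation magnitudes were available to copy. Trabecular: exchangeable
  $|r| = 0.6$ with Tb.Sp anticorrelated. Cortical: 0.7 among the size
  variables, weak (0.1-0.3) couplings for Ct.Ar/Tt.Ar, Ct.Th and Ct.TMD,
  with the area fraction negatively related to marrow size. Both
  matrices are verified positive definite at config time.
* **Model-specific baselines** emulate background-strain offsets, so
  pooling raw values across models is visibly wrong without
  standardization.
* **Unbalanced designs** via a per-cell `n` table; typical group sizes in
  this field run 9-21 per cell, and the examples use 8-12.
* **A uniform "subclinical deficit"** moves every variable in its own
  deficit direction: down for BMD, BV/TV, Tb.Th, Tb.N and *up* for Tb.Sp
  (higher separation is the deficit — the same fact that reverses its
  loading sign). `composite_power_study()` implements this; shifting
  Tb.Sp down with the others would simulate a pattern orthogonal to the
  biology.
* Missing-data injection is an explicit option exercising the
  complete-case drop rules.
* All randomness flows through R's default Mersenne-Twister generator
  from a mandatory integer seed; identical config and seed give
  byte-identical output.

Synthetic bend curves are piecewise linear with an optional sub-preload
toe and Gaussian force noise; synthetic masks are pixel-center-exact
annuli. Both record their generating truth for recovery studies.

**What passing tests do and do not show.** The generator produces
Gaussian panels with a homogeneous correlation structure, linear effects
and clean factorial designs. Real micro-CT data have skewed variables,
heteroscedastic groups, batch structure beyond a model offset, and
measurement artifacts. Green tests therefore validate the *machinery* —
formulas, decompositions, decision rules, calibration under the stated
model — not the biological adequacy of any particular dataset.

## Calibration and power properties

Three simulation studies are rerun by `scripts/acceptance.R` and the test
suite at fixed problem sizes chosen to keep the full suite under a minute
of simulation time while leaving Monte-Carlo error well inside the
asserted bands:

* **Null calibration** (1000 replicate cohorts, n = 10/group, zero
  effects): the genotype rejection rate on trabecular composite scores
  stays within 0.05 ± 0.02.
* **Sign-structure recovery** (200 replicates, n = 12/group): the
  oriented PC1 shows the four-positive/Tb.Sp-negative pattern in at
  least 95% of replicates (observed: 100%).
* **Subclinical detection** (500 replicates, n = 12/group, uniform
  0.4 SD deficit): the composite-score t test is more powerful than the
  best Sidak-corrected univariate test (about 21% versus 14% at these
  settings). The advantage grows with the number of affected variables
  and their correlation; with a deficit confined to one variable the
  univariate test would win — the composite is a test of *overall*
  compartment state, not a uniformly better test.

## Numerical conventions and edge cases

* Ties: first occurrence wins for the ultimate-force argmax; the
  stiffness window tie order is earlier start, then larger window.
* Degenerate inputs fail loudly and name the offender: zero-SD
  standardization strata, constant PCA columns, empty factorial cells,
  zero-variance Welch groups, masks without a cavity, rays that never
  cross cortex.
* Eigen-decomposition is delegated to `prcomp` (SVD-based); tests verify
  it against an explicit covariance eigendecomposition at `1e-10`.
* Adjusted p-values are capped at 1 and never fall below the raw p.
* Strata with fewer than two animals, or animals missing panel cells,
  are excluded with logged reasons; the pipeline accounts for every
  input animal in either the scores or the exclusion log.

## Known limitations

* PC1-only scoring: when the leading component explains little variance
  (diffuse correlation structure), a single composite under-summarizes
  the panel; the variance-explained diagnostic should be checked before
  interpreting scores.
* The Welch reassessment is one-way across a term's marginal groups, not
  a heteroscedastic factorial model.
* Cortical thickness is a 2D radial definition on a single section, not
  the 3D local-thickness measure some imaging pipelines report; the two
  agree on idealized geometries but can differ on irregular sections.
* The repeated-measures machinery for longitudinal body weights
  (sphericity corrections and related) is out of scope, as is 3D
  trabecular morphometry and density calibration from attenuation —
  density variables enter as tabular inputs only.
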