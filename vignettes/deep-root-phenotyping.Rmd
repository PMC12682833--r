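---
title: "Deep-rooting traits and isotope tracer accounting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-rooting traits and isotope tracer accounting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeproot)
library(dplyr)
```

## The measurement problem

Semi-field root phenotyping facilities grow crop rows above transparent
minirhizotron tubes installed at a shallow angle, so that a camera pulled
through each tube photographs roots from the topsoil down to several
metres. Automated segmentation of those images yields a root length per
image, and because the tube position of every image is known, a
depth-resolved *root profile* per crop row. Deep placement of stable
isotope tracers — `15N`-labelled nitrate and `2H`-labelled water injected
at 1.6–1.8 m — turns the same rows into a functional assay: enrichment of
grain and straw above natural abundance measures how much deep N and
water each genotype actually took up, while tissue `delta13C` integrates
stomatal behaviour over grain filling and therefore water stress.

`deeproot` implements the full chain from per-image observations to
genotype-level inference: depth registration and pixel calibration,
deep-rooting traits, tracer mass balance, and the cultivar-mean
correlation and genotype-mean analyses. A synthetic-trial generator with
known ground truth stands in for raw field data, which for this kind of
study is typically not released, and makes every stage testable.

## Depth registration and observation area

A tube is described by `tube_geometry()`. Depth registration is **linear
between two anchors**: the soil depth of the shallowest image (0.6 m by
default) and the depth at the far end of the tube (3.0 m at 5500 mm).
The nominal 24° installation angle is deliberately not used: a 5.5-m tube
at exactly 24° would drop only `5.5 * sin(24°) ≈ 2.24` m, which is
inconsistent with the stated endpoint depths, so the anchors take
precedence and the angle is metadata. Facility descriptions also quote
2.7 m of observable depth at the bed centre; both endpoints are exposed
as configuration and 3.0 m (the imaging convention) is the default.

Depth intervals are half-open `[lo, hi)` throughout, which makes any
binning of images a partition: interval root lengths and observation
areas are exactly additive, and a bin boundary can never double-count an
image.

The observation area of a depth interval is
`n_images x image_step_mm x image_width_mm`. No image width is printed
in facility descriptions; the default (240/11 ≈ 21.8 mm) is derived by
inverting this formula against the stated 0.0125 m² of observation area
per 0.25 m depth interval, using the mean image density (16.37 images
per 0.25 m of depth). With discrete image counting an individual 0.25-m
window holds 16 or 17 images, so the round-trip reproduces 0.0125 m² to
within one image's area.

## Deep-rooting traits

**DeepRoot40.** Let $C(d)$ be the cumulative root length observed at
depths $\ge d$. The trait is the greatest depth $d^\*$ with
$C(d^\*) \ge 40$ cm — the depth *below which* a substantial amount of
root is still seen. Deeper-rooted rows score higher. Each image's length
is anchored at its image depth and $C$ is taken piecewise linear between
adjacent image depths, so the crossing is solved within the crossing
image rather than quantized to the 35-mm grid:

$$d^\* = d_j + \frac{S_j - T}{\ell_j}\,(d_{j+1} - d_j),$$

where $S_j$ is the bottom-up cumulative sum at image $j$ (the deepest
image with $S_j \ge T$) and $\ell_j$ its length. Whether the original
trait definition interpolates or reports grid depths is not stated
anywhere we could check; the two differ by at most one image interval
(~1.5 cm of depth), and the test suite bounds our implementation against
an independent 1-mm grid scan of the same interpolated curve to 0.5 cm.
A tube with less than 40 cm of total root has an undefined trait — `NA`
with a reported shortfall, never a boundary value — and undefined values
propagate as missing with pairwise deletion in all correlations.

**Sigmoid inflection.** `fit_root_sigmoid()` fits
$y(d) = A / (1 + e^{k (d - m)})$ to per-image root length against depth
(cm) by bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). The inflection $m$ marks the transition from
dense shallow to sparse deep roots. The exact parameterization used by
earlier work on this trait is not published; this logistic form is the
package's documented choice. Initialisation is $A_0$ = 95th percentile
of $y$, $m_0$ = length-weighted median depth, $k_0 = 4/\text{range}$;
$m$ is constrained to the observed depth range and $k \in (0, 5]$.
Non-convergence, an $m$ pinned at a bound, or a near-constant profile
(CV < 0.05, "no depth transition") all yield `NA` with a diagnostic —
never a silently returned boundary value. On exact logistic data the fit
recovers $(A, k, m)$ to relative error below $10^{-3}$; under
multiplicative noise of CV 0.3 the median error in $m$ is ~5 cm on a
140-image tube.

**pRLD.** `bin_profile()` sums root length in 0.30-m depth bins and
divides by the bin's observation area in cm², giving planar root length
density (cm of root per cm² of image). Bins without images are `NA`
(undefined), not zero; bins with images but no roots are zero.

## Isotope arithmetic

`delta_to_atom_fraction()` applies the standard identities
$R = (\delta/1000 + 1) R_{std}$ and $AF = R/(1+R)$, with the literature
standard ratios (air N₂ 0.0036765, VPDB 0.0111802, VSMOW 0.00015576) as
configurable constants. Excess (tracer-derived) `15N` in a sample is

$$\text{excess} = m_{dry} \cdot \frac{\%N}{100} \cdot
  \left(AF(\delta^{15}N) - AF(\delta_{baseline})\right),$$

with the unlabelled baseline defaulting to 0 ‰ against air (no control
plot values being available) and configurable to a measured baseline.
Slightly negative excess values, possible within measurement noise, are
flagged but never clamped, so that averages stay unbiased.

Recovery divides a row's summed excess by the tracer applied per row.
The printed per-row-side amounts (0.00759 g `15N`, 5 mL `2H₂O`) equal
the mixture totals divided by 200 row sides; the per-row applied dose is
taken as `total x n_injections / 300 rows` with `n_injections = 3`, the
value that makes the per-row dose equal twice the per-row-side dose
(0.0151725 g). The physical basis of the 200 divisor is not explained in
the source material; the defaults reproduce the printed numbers and
every divisor is configurable. Grain-only and grain-plus-straw
recoveries are reported separately. `delta13C` is carried through
unchanged (no discrimination conversion), and the model transforms are
$\ln(\delta^{15}N)$ and $\ln(\delta^2H + 90)$, the +90 shift
accommodating negative water deltas.

## Genotype-level statistics

The original analyses of this design use generalized least squares with
a row/bed/year spatial correlation structure and estimated marginal
means. That machinery is **intentionally not reproduced**:
`estimate_genotype_means()` fits a fixed-effects linear model — genotype
plus year and bed factors and a quadratic along-bed position covariate —
and extracts marginal genotype means via `emmeans`. The divergence is
recorded in the returned object's metadata. The correlation-structure
family such a gls would need is not stated in the material this package
is built from, and guessing one would add unverifiable complexity; the
fixed-effects surrogate captures the design's systematic spatial terms
and recovers planted means exactly on balanced noiseless data.

Pairwise genotype comparisons use Tukey adjustment when the genotype
design is balanced and Holm otherwise. The compact letter display is
computed in-package by the insert-and-absorb algorithm on the
significance graph; a property test asserts the defining invariant —
two genotypes share a letter *iff* their adjusted pairwise p-value is at
least α (default 0.05). Letters are ordered so that the deepest-rooting
(largest) mean carries "a".

Replication filtering follows the two published rules: genotypes with
≥ 4 replicate rows within a year enter the correlation analyses
(per-year scope); genotypes with ≥ 4 replicates in *every* year enter
the genotype-mean models (all-years scope). Cultivar-mean Pearson
correlations use pairwise deletion and two-sided p-values from the
t-distribution on $n-2$ df; zero-variance series give a flagged
undefined result rather than NaN.

## The synthetic trial generator

`simulate_trial()` emulates the study design: two beds, 9 core genotypes
× 10 rows plus 39 genotypes × 4 rows (246 rows/year, 48 genotypes),
with genotype labels persistent across simulated years.

*Root profiles.* Expected root length per image follows a logistic
depth decay $A_g / (1 + e^{k_g (d - m_{g})})$ — the same family the
sigmoid-inflection trait presumes, which keeps the generator and the
trait model honest about each other. Genotypes differ in three ways:
a midpoint shift $b_g \sim N(0, \sigma_b)$ (default 10 cm), a lognormal
steepness factor on $k$ (default SD 0.15) and a lognormal surface scale
on $A$ (default SD 0.1). The steepness variation matters: with midpoint
shifts alone, root lengths at all deep intervals are collinear across
genotypes and no depth-interval screen could localize an uptake signal
even in principle. Rows add a bed offset (3 cm), a smooth sinusoidal
along-bed trend (3 cm) and midpoint jitter (4 cm); each image
observation is multiplied by lognormal noise (SD 0.3), keeping lengths
non-negative. With defaults, $A = 2$ cm, $k = 0.05$ cm⁻¹ and
$m_0 = 120$ cm give whole-tube root lengths near 80 cm and DeepRoot40
means near 98 cm with a between-row SD of ~5.5 cm — the scale observed
in modern winter wheat panels. Optional per-year midpoint shifts
(0, −22, −5 cm) reproduce the qualitative year ranking of deep rooting.

*Isotopes.* The per-row tracer uptake fraction is
$u = u_0 (L_{obs}/L_{ref})^{\beta_1} e^{\varepsilon}$, coupled to the
**realized** root length in the 1.6–1.8 m injection interval
($\beta_1 = 1$ by default; $\beta_1 = 0$ decouples it for null
calibration). Tissue `delta15N` is then derived by *inverting* the
excess mass balance from $u$ times the per-row dose, split 85/15
between grain and straw. Two properties follow by construction:
log-transform domains are always valid, and aggregate recovery computed
by the isotope module equals the planted aggregate uptake fraction
exactly — conservation is a structural identity, and the test suite
verifies the round trip to $10^{-6}$. With realistic grain N masses
(~75 g × 2.1 %N) the default $u_0 = 0.008$ puts grain `delta15N` around
+20 ‰, matching the order of magnitude of enriched field tissue.
`delta2H` rises from the −90 ‰ floor with uptake; `delta13C` declines
with expected DeepRoot40 at 0.018 ‰/cm, scaled by a per-year drought
severity multiplier (1, 0.4, 1.8) so the dry-year correlation is
strongest — a scalar stand-in for a mechanistic water model, chosen
deliberately.

*What the generator does not emulate:* weather and soil-moisture
dynamics, yield formation, spatial autocorrelation beyond the smooth
bed trend, root diameter or branching, segmentation artefacts, or
measurement error in isotope-ratio mass spectrometry. Passing tests
therefore demonstrate that the *analysis chain* is correct and
well-calibrated under the stated statistical structure — not that field
data of this design would show these effect sizes.

## Numerical conventions and degenerate inputs

- Bin and interval edges are half-open; conservation of summed root
  length across bins is exact up to floating-point associativity.
- The DeepRoot40 crossing solve and its grid-scan oracle agree to grid
  resolution (0.1 cm); both cap at the deepest observation when the
  bottom image alone meets the target.
- Empty profiles, duplicate tube positions, inverted intervals,
  out-of-range positions, negative lengths and non-physical deltas
  (≤ −1000 ‰) are errors, reported with offending values or file line
  numbers; undefined *results* (trait shortfall, flat profile,
  zero-variance correlation) are `NA` with a reason, and never abort.
- All simulation randomness flows through a single integer seed
  (`withr::with_seed`); identical configuration and seed give
  byte-identical CSVs.

## Problem sizes used by the test suite

The suite exercises the defaults at reduced replication to keep a full
run near two minutes: 200 random profiles for the grid-scan oracle, 500
cases for the threshold monotonicity property, 50 noisy replicates for
sigmoid recovery, 50 coupled and 200 null trials (each 246 rows × 158
images) for the correlation detection and calibration checks, and 500
balanced 9 × 10 trials for the letter-display power check against the
planted 25.3-cm extreme-genotype contrast.

## Known limitations

- The fixed-effects spatial surrogate understates standard errors
  relative to a gls with a fitted correlation structure when residuals
  are strongly autocorrelated along a bed.
- DeepRoot40 underestimates true rooting depth by construction (it is a
  cumulative threshold, not a root-front estimate), and comparisons
  across facilities with different observation areas require rescaling
  the 40-cm target.
- The generator's uptake model is phenomenological; it preserves signs,
  orderings and mass balance, not transport physiology.
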