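---
title: "Predicting the gingerol:shogaol ratio from hyperspectral images: models and methods"
author: "gingerHSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the gingerol:shogaol ratio from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gingerHSI)
```

## The problem

The pungency and market quality of dried ginger powder are governed by two
compound classes: 6-gingerol, the dominant pungent constituent of fresh
rhizome, and 6-shogaol, its dehydration product formed during drying and
heating. Their unitless ratio is a quality indicator, but measuring it
requires destructive, slow HPLC chemistry. Vis-NIR hyperspectral imaging
(HSI) offers a non-destructive alternative: a camera records a full
reflectance spectrum (here 204 bands across roughly 400-1000 nm) at every
pixel of an image of the powder, and chemometric regression maps the
spectra onto the reference ratio.

`gingerHSI` implements that pipeline end to end: reflectance calibration of
ENVI datacubes, region-of-interest (ROI) mean-spectrum extraction, spectral
pre-treatments, PLSR and LASSO regression with cross-validated
hyperparameters, wavelength selection, and evaluation by R², RMSE, RPD and
limit of detection. Because the physical ginger samples behind the original
measurements are not publicly archived, the package ships a synthetic-cube
generator that reproduces the *statistical structure* the analysis assumes
and serves as the test substrate for every downstream stage.

## The synthetic forward model

Each simulated sample has a pure reflectance spectrum

$$r(\lambda) = \mathrm{baseline}(\lambda)
  - c_g \, A_g(\lambda) - c_s \, A_s(\lambda),$$

clipped to [0.02, 0.98], where $A_g$ and $A_s$ are sums of Gaussian
absorption bands (Beer–Lambert-style, linear in concentration) for
gingerol and shogaol, placed at non-collinear positions across the Vis-NIR
range. The camera sees digital numbers

$$DN = \mathrm{gain}(\lambda)\,\big(a\,r(\lambda) + b\big)
  + \mathrm{dark}(\lambda) + \varepsilon,$$

with a smooth band-dependent gain and dark level, *per-sample*
multiplicative/additive scatter $a \sim N(1, 0.08)$, $b \sim N(0, 0.03)$,
and per-pixel noise $\varepsilon$ with reflectance-scale SD 0.02. The white
frame is `gain + dark`, the dark frame `dark`, so applying the calibration
equation recovers $a\,r + b$ plus noise exactly — the closure property the
tests assert.

Two modelling choices deserve emphasis:

* **Scatter is per sample, not per pixel.** Packing density and particle
  size vary between powder samples, not between neighbouring pixels; and
  only sample-level scatter survives ROI averaging. Per-pixel scatter
  would be annihilated by the 64 × 64 ROI mean, leaving SNV and MSC with
  nothing to correct — contradicting the premise of the whole
  pre-treatment comparison.
* **Concentrations are log-normal**: gingerol with meanlog $\log 7.5$ and
  sdlog 0.5 mg/g, shogaol with meanlog $\log 5$ and sdlog 0.15. No
  published numeric ranges exist for these samples, so the defaults are an
  acknowledged invention chosen once: they give a ratio spanning roughly
  0.5–4 with median ≈ 1.5, wide enough that limits of detection near
  0.6–1.0 are meaningful, and with most ratio variance driven by gingerol
  (the biologically dominant axis of variation between fresh and aged
  powder). The narrow shogaol spread also bounds the intrinsic
  nonlinearity of the ratio: a linear model can explain at best about
  $1 - \mathrm{CV}_s^2 \approx 0.98$ of the ratio variance, leaving
  headroom for the recovery checks without making them trivial.

What the generator does **not** emulate: real ginger spectral shapes
(water, starch and fibre bands), instrument wavelength-registration drift,
spatial heterogeneity of the powder surface, stray light, or detector
nonlinearity. Passing tests therefore demonstrate that the *chain of
methods* is implemented correctly and recovers planted signal under
realistic noise — not that this level of performance would replicate on
real ginger in the field.

## Calibration and spectrum extraction

Raw cubes are converted to relative reflectance per pixel and band:

$$I_c = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}}.$$

The white tile's nominal 99% reflectance is *not* divided out; the
constant is absorbed by the regression. Pixels whose denominator magnitude
falls below `eps` (default 1e-10 DN) become `NA`, are counted in a
diagnostic, and are excluded band-wise from the ROI mean; more than 1% of
degenerate pixels triggers a warning. Reference frames may be full cubes
or per-band vectors (the dark level of this camera class is recorded
internally as a per-band quantity). ROI coordinates are 0-based and
half-open, matching common imaging conventions; the ROI is always
user-supplied — no automatic segmentation is attempted.

## Pre-treatments

Seven named transforms plus the untreated spectrum make up the canonical
grid. All act row-wise on the sample × band matrix and preserve its shape
and wavelength axis.

* **SNV** centres and scales each spectrum to unit SD (sample SD, K−1
  denominator — documented so the oracle tests agree exactly).
* **MSC** regresses each spectrum on a reference by OLS and inverts the
  fitted affine map. The reference is the column mean of the *training*
  split only and is applied frozen to test spectra; fitting it on all
  samples would leak test information into the transform.
* **MF5 / MF9 / MF11** are one-dimensional centred moving averages along
  the band axis with truncated edges. The "mean filter" of imaging
  pipelines admits a spatial reading too; since the treatments here are
  applied to the *averaged* spectra, the 1-D reading is canonical, and a
  per-band spatial filter (`spatialMeanFilter()`) is available separately
  for the cube-domain variant. Widths 5 and 9 are the named variants;
  width 11 also appears in the canonical grid (below).
* **SG1 / SG2** are Savitzky–Golay convolution derivatives: first
  derivative with window 11 / polynomial order 2, second derivative with
  window 11 / order 3. The source methods do not state window or order;
  these are common chemometric defaults and both are configurable.
  Derivatives are divided by the band spacing raised to the derivative
  order, giving per-nm units. Implementation rides on
  `signal::sgolayfilt()`; the tests check it against a from-scratch
  per-window polynomial least-squares oracle, including the one-sided
  edge fits, and against exactness on polynomials up to the fitted order.

## The train/test split

Samples are split 80/20 by a seeded uniform permutation
(`round(0.2 * 89) = 18` test samples), seed 20 by default in honour of the
original analysis' random state. The permutation algorithm is R's, so the
membership cannot be identical to a split produced by another language's
RNG — the seed fixes *our* split reproducibly, nothing more. Every cell of
the model grid shares the one split: the study design splits once, then
compares models.

## PLSR

Single-response PLS1 fitted by NIPALS on mean-centred data. Per component:
weight $w \propto X^\top y$ (unit norm), score $t = Xw$, loadings
$p = X^\top t / t^\top t$, $q = y^\top t / t^\top t$, then deflation of
both $X$ and $y$. The regression vector is
$\beta = W (P^\top W)^{-1} q$; prediction through $\beta$ and through the
score pathway agree to machine tolerance, scores are mutually orthogonal,
and $X = TP^\top + E$, $y = Tq + f$ hold exactly — all asserted as
invariants. A component whose score norm collapses below 1e-12 stops the
decomposition early with a warning.

The latent-variable count J is chosen by leave-one-out cross-validation
over J = 1..20 (capped at min(N−2, K)); ties go to the smallest J. At
J = rank(X) the fit coincides with OLS, which the tests use as an anchor.
Predictors are centred but not variance-scaled, symmetrically with LASSO;
an autoscaling flag was considered and rejected because the pre-treatments
already normalise scale where that is intended.

Independent cross-checks: a SIMPLS implementation living in the test
helpers (different algorithm, identical predictions for one response) over
100 random problems, and `mixOmics::pls()` on a fixture.

## LASSO

The objective is the *unscaled* penalised least squares

$$\sum_i \Big(y_i - \sum_j X_{ij}\beta_j\Big)^2 + \alpha \sum_j |\beta_j|,$$

solved by cyclic coordinate descent with soft thresholding on centred
data. Users of libraries whose objective carries a $1/(2N)$ factor should
translate penalties as $\lambda = \alpha / (2N)$; the glmnet cross-check
test encodes exactly that mapping. The full-shrinkage penalty is
$\alpha_{max} = 2\max_j |X_j^\top y|$, the top of the default 50-point
log-spaced grid ending at $10^{-4}\alpha_{max}$. $\alpha$ is selected by
leave-one-out cross-validation — k-fold is more common for LASSO, but the
latent-variable selection uses leave-one-out and the same scheme is applied
to both models deliberately. Ties go to the *largest* α (sparser model).
At α = 0 the solver returns the minimum-norm least-squares solution via an
SVD pseudoinverse, since coordinate descent does not guarantee minimum
norm under rank deficiency.

### Numerical behaviour on collinear spectra

Smoothed reflectance spectra have adjacent-band correlations within
rounding of 1, and coordinate descent on such designs has a pathology
worth documenting: the objective and the KKT residuals settle quickly,
while the coefficients keep drifting along nearly flat directions of the
objective essentially forever. A pure max-coefficient-change criterion
(default tolerance 1e-8) therefore cannot terminate on these inputs at any
reasonable sweep budget. The solver consequently stops on whichever comes
first:

* a full pass changes no coefficient by ≥ 1e-8 (the primary rule — the
  only rule that engages on well-conditioned problems, which is why the
  KKT residuals of ordinary fits sit far below 1e-6); or
* after 500 passes, every KKT residual is below 3e-5 of the gradient
  scale $\max_j|X_j^\top y|$ (the last-resort rule; measured plateaus on
  smoothed ginger spectra sit around 1e-5 of that scale with duality gaps
  below 1e-4 of the objective).

Inside the cross-validation loop the tolerances are looser (coefficient
change 1e-5, anytime KKT 1e-3 of the gradient scale): tightening both by
an order of magnitude moves the CV RMSE curve by under about 1% and costs
more than an order of magnitude in sweeps, and the selected α only moves
within the flat basin of the CV curve. The model finally reported is
always refitted at the strict tolerances. Exceeding the sweep budget
(1e5) raises an error carrying a duality-gap diagnostic. The active-set
iteration strategy (full passes alternating with passes over the non-zero
coordinates) follows the standard practice of compiled LASSO solvers, and
the inner loop is C++ for the same reason those solvers are compiled: the
grid's leave-one-out α search alone fits roughly 28,000 path problems.

## Wavelength selection

Two methods, both computed from the training fit only:

* **β-coefficient**: discard bands whose |β| falls below the SD of all
  β-coefficients. The SD uses the population (1/K) denominator by default
  (configurable; the retained set rarely differs). Bands exactly on the
  threshold are retained — "less than" discards, so equality keeps.
* **VIP**: the standard single-response formulation,
  $VIP_j = \sqrt{K \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}$ with
  $SSY_a = q_a^2 t_a^\top t_a$. This is the formula the conventional
  threshold of 1 presupposes, because it is mean-square normalised:
  $\tfrac1K\sum_j VIP_j^2 = 1$, so at threshold 1 the retained set can
  never be empty. The identity is asserted for every fitted model.

After selection the band subset is applied to both splits and the
latent-variable count is re-selected by leave-one-out CV on the reduced
training matrix. LASSO gets no selection stage — it performs its own.

## Evaluation

R² uses the standard form $1 - \sum(y_p - y_m)^2 / \sum(y_m - \bar y)^2$.
A variant with the *predicted*-deviation denominator exists in the
literature this package mirrors; it conflicts with its own legend and can
exceed 1, so it is available behind `printed_form = TRUE` for
compatibility and is not used anywhere else. RMSE uses the 1/m
denominator. RPD is SD/RMSE per split with the SD taken over the
*predicted* values — unusual but unambiguous in the source convention —
with `sd_of = "measured"` for the conventional variant. A testing RPD of
at least 1.4 flags the model "good". The limit of detection is
$3 \times RMSE_{cal} / slope_{cal}$ with both quantities from the training
(calibration) split and the slope defined as the OLS slope of predicted on
measured — the usual meaning of "slope of the calibration" in multivariate
calibration. A perfect fit reports an infinite RPD rather than failing.

## The model grid

The canonical grid enumerates eight pre-treatment variants
{raw, SNV, MSC, MF5, MF9, MF11, SG1, SG2} × {PLSR, LASSO} = 16 models,
plus {β-coefficient, VIP} selection refits of each PLSR fit = 16 more,
for 32 rows. The named treatment list of the source methods section has
seven entries including "raw"; its results section mentions an MF11
variant, which completes the eight-variant arithmetic, so MF11 fills the
eighth slot here. The treatment list is configuration, not hard-coded, and
the row-count formula |treatments| × 4 holds for any subset.

A failing cell records its error message in the results row and the grid
continues — one degenerate fit should not kill a 32-cell comparison. The
manifest carries the sample and band counts, split definition,
hyperparameter search sizes, a configuration hash and package/R versions;
given a dataset and seed, every output byte is reproducible, and the test
suite asserts byte-identical CSV across reruns.

## Problem sizes and runtimes

The acceptance-grade checks run the full study geometry: 89 samples of
64 × 64 × 204 cubes (simulation ≈ 15 s) and the complete 32-cell grid
(≈ 45 s on one core). Module tests use smaller geometries — 8–40 samples,
25–60 bands, 4 × 4 to 16 × 16 cubes — chosen so each file runs in seconds
while still exercising every code path. Oracle comparisons use 20 × 10
random problems (100 seeds for the PLS reference check, 50 fits for the
VIP identity).

## Known limitations

* The generator's spectra are schematic (smooth baseline + Gaussian
  bands); no claim is made that models trained on them transfer to real
  ginger.
* ENVI support covers the uncompressed float dialect with BSQ/BIL/BIP
  interleaves only — no tiled, compressed or integer formats, and no
  vendor-specific metadata interpretation.
* Coordinate-descent convergence on extremely collinear designs is
  accepted at the documented late KKT threshold; coefficient *values* in
  flat directions are then determined only up to that tolerance, although
  predictions are stable far below it.
* Leave-one-out selection of α is faithful to the design being mirrored
  but is known to be a high-variance selector; k-fold would be the usual
  recommendation for new work.
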