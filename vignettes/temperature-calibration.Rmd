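---
title: "Estimating charring temperature of archaeological charcoal from FT-MIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating charring temperature of archaeological charcoal from FT-MIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Wood charcoal from archaeological deposits carries a chemical imprint of the
maximum temperature it reached during combustion. Mid-infrared (ATR FT-MIR)
absorbance spectra of powdered charcoal record that imprint: as charring
temperature rises, carbonyl and polysaccharide bands fade while aromatic
carbon bands grow. `pyrocal` turns this into a quantitative thermometer.
For each wood taxon, sound modern wood is charred in a muffle furnace at a
grid of known temperatures (350–600 °C in 50 °C steps, the typical range of
wood fires), its spectra form a calibration set, and a latent-variable
regression maps spectrum to temperature. Archaeological charcoal of the same
taxon is then measured on the same instrument and its burning temperature
predicted. Alongside the thermometry, the package quantifies the charcoal
assemblage itself (fragment counts per taxon and stratigraphic unit, with
ubiquity-corrected frequencies), since both lines of evidence are read
together when interpreting a combustion feature such as a cremation pyre.

## The calibration model

Spectra are restricted to the fingerprint window 1800–400 cm⁻¹ and linearly
interpolated onto a common 250-point descending grid (spacing ≈ 5.6 cm⁻¹).
The raw acquisition range and resolution (4000–400 cm⁻¹ at 2 cm⁻¹) are much
finer; the analysis window and point count follow standard chemometric
practice of working on a reduced uniform grid. Interpolation never
extrapolates: a spectrum must span the window.

Preprocessing is the standard scatter-correction stack, applied in this
order:

1. **Standard normal variate (SNV)** per spectrum: subtract the spectrum's
   mean and divide by its sample (n−1) standard deviation. This removes
   multiplicative scatter and additive baseline offsets.
2. **Median filter** per spectrum (default window 5 grid points ≈ 28 cm⁻¹,
   edge-replication padding): removes 1–2-point noise without erasing
   bands, which are several grid points wide. The window is configurable
   and must be odd; window 1 disables filtering.
3. **Mean centering** per wavenumber, with column means estimated from the
   calibration set only. The temperature response is centered by its mean
   likewise. All constants are stored, and new spectra are transformed with
   the *stored* state — held-out or archaeological spectra never contribute
   to the centering, so there is no train/test leakage.

The regression is PLS1 fitted by NIPALS deflation. Per latent factor *f*,
the weight vector is w ∝ Xᵀy (unit norm), the score t = Xw, the x-loading
p = Xᵀt/tᵀt, the y-loading q = yᵀt/tᵀt, after which X and y are deflated by
the extracted factor. Training scores are mutually orthogonal, and at
F = rank(X) the fit coincides with ordinary least squares — both properties
are pinned in tests, together with agreement against an independent PLS
implementation. Prediction accumulates q-weighted scores obtained by
sequential deflation with the stored weights and loadings (equivalently, by
the accumulated regression vector; both code paths are tested for
agreement) and adds back the calibration mean temperature. Predictions are
**not clipped** to the calibration range; extrapolation only raises a
warning, because genuinely hotter or cooler events must remain visible in
the estimates.

## Factor selection and honest cross-validation

The number of latent factors is chosen by leave-one-out cross-validation —
forced by the design, which has only six calibration samples per taxon.
Inside each fold the preprocessing state and the PLS fit are re-estimated
on the remaining five samples. RMSECV(F) is summarised by
AIC = n·ln(RMSECV²) + 2·(F+1), a standard small-sample penalised form
(the exact functional form used by legacy chemometrics software is not
documented; any fixed monotone variant would order models similarly, and
the default is pinned by tests). The smallest F attaining the minimum AIC
is selected — parsimony on ties. Model quality is reported as the squared
Pearson correlation of the cross-validated predicted-versus-observed pairs,
with a two-sided t-test p-value on n−2 degrees of freedom; the alternative
1 − SSE/SST definition differs slightly but the squared correlation matches
the conventional reporting of calibration plots.

One numerical subtlety is worth recording: for completely uninformative
spectra every held-out prediction is the training-fold mean, and fold means
are perfectly *anti*-correlated with the held-out values, so the squared
correlation of that degenerate predictor is 1 even though RMSECV is huge
(≈ 102.5 °C on the 350–600 grid, a closed form pinned in tests). The
permutation test below is immune to this artefact because observed and null
fits share the statistic, but the r² of a rejected model should never be
read in isolation.

Because SNV and the median filter act on each spectrum independently, they
are computed once and shared across folds and permutations; only the
centering and the PLS fit are re-estimated. This is an exact optimisation,
not an approximation, and it is what keeps the permutation machinery fast
enough to run hundreds of full pipelines in seconds.

## Permutation validation

With six samples a four-factor PLS model can fit almost anything, so every
calibration is challenged by a randomised-response test: the temperatures
are shuffled, the entire pipeline (preprocessing refit, LOO CV, AIC factor
selection) is rerun, and the cross-validated r² of each shuffled fit forms
the null distribution. The p-value uses the add-one formula
(1 + #{null ≥ observed})/(n_perm + 1), which can never be zero. The default
is 199 random shuffles (sampling permutations with replacement — at n = 6
there are only 720 distinct orders, and an exhaustive mode is available for
n ≤ 7); the permutation statistic is always the honestly re-selected
cross-validated r², never the observed model's factor count. A model is
accepted when p < α (default 0.05), and prediction from a rejected model is
refused unless forced. Under a true null the p-values are uniform, a
calibration property checked by Monte Carlo in the acceptance tests.

## Variable importance and diagnostic bands

VIPⱼ = sqrt(p · Σ_f SS_f w²ⱼf / Σ_f SS_f), with SS_f the response variance
captured by factor f, summarises each wavenumber's contribution; squared
VIPs sum to p by construction, so 1 is the mean-square reference level.
Diagnostic bands are reported as local maxima of the VIP trace above a
threshold (default 1), thinned to a minimum separation (default 25 cm⁻¹).
Two details matter. The median-filtered pipeline produces flat-topped VIP
peaks, so plateaus are treated as single maxima; and because tiny noise
decides the argmax along a plateau, the reported position is the
VIP-weighted centroid of the peak's own hill (the points reachable by
non-increasing descent from the maximum), which is stable to a fraction of
a grid step. A perfectly flat trace yields no bands.

## Group predictions and comparisons

Archaeological replicate spectra of one taxon in one stratigraphic unit are
predicted individually and summarised by unrounded mean, minimum and
maximum; rounding (half away from zero, matching how such tables are
printed) happens only at report time. Between-taxon contrasts within a unit
use classical one-way ANOVA followed by Tukey–Kramer pairwise comparisons
on the studentized range distribution (exact for unequal group sizes), with
a compact letter display: groups share a letter exactly when their adjusted
p exceeds α, letters assigned from the largest mean downwards by an
insert-and-absorb construction whose consistency with the pairwise tests is
verified exhaustively for up to five groups. Within-taxon contrasts across
units are plain differences of group means.

## Assemblage quantification

Counts are stored per taxon × stratigraphic unit. Relative frequency is
%A(SU) = 100·N_A(SU)/N(SU); the overall percentage uses summed counts. The
ubiquity-corrected value %U(A) is the plain mean of the per-SU percentages,
*including zeros for units where the taxon is absent* — this is what makes
%U weight presence-across-contexts rather than raw abundance, and it is
required to reproduce published values for taxa confined to a single unit.
Unrounded per-SU percentages enter the mean; all printed cells of the
reference assemblage reproduce under one-decimal half-away-from-zero
rounding, with two documented exceptions where the source table itself
truncates (a combined shrub share of 8.49 printed as 8.4, and a feature
prevalence of 37.28 printed as 37.2) and one evident typographical cell
(a per-unit percentage printed as "317" where the counts give 31.7). The
minimum-taxa count per unit excludes labels identifiable only above the
taxon level (e.g. "Angiosperm").

## The synthetic generator

No archaeological spectra are distributed with instrument data, so the
package ships a generator that emulates the calibration design: a spectrum
is a sum of Gaussian bands (σ = 12 cm⁻¹) whose peak amplitudes vary
linearly with charring temperature around a 475 °C anchor (the grid
midpoint, so slopes read as symmetric deviations), on a sloping baseline,
scaled by a per-spectrum log-normal scatter factor (sd 0.05) and corrupted
by additive Gaussian noise (sd 0.005 absorbance). Per-taxon presets place
temperature-sensitive bands at each taxon's diagnostic wavenumbers (Olea:
1730, 1580, 1410, 800, 740 cm⁻¹; Quercus: 1580, 1410, 1370, 800, 740 with
an insensitive 1730; Pinus: 1730, 1410, 1370, 1245, 1040), with slope signs
chosen on chemical grounds — carbonyl (1730), polysaccharide (800, 740),
resin-acid (1245) and C–O (1040) bands decay with temperature, aromatic
bands (1580, 1410, 1370) grow — and insensitive filler bands at 1570, 1380,
1270 and 1040 cm⁻¹ for realism. A filler within 20 cm⁻¹ of a preset band is
not duplicated: two Gaussians 10 cm⁻¹ apart at σ = 12 are sub-resolution
and would be a single physical band. Base amplitudes lie in 0.2–1.0
absorbance and slopes are ±4×10⁻⁴ absorbance/°C; all of these are the
package's own invented fixture constants, not measured values.

With noise and scatter off, the map temperature → spectrum is exactly
affine, so PLS's linearity assumption holds exactly and two calibration
points determine any third temperature — the generator can therefore
provide exactness oracles as well as noisy stress tests. What it does *not*
emulate: nonlinear band saturation, temperature-dependent band widths or
positions, ATR contact variability beyond a global scatter factor,
correlated (pink) noise, and any between-specimen biological variability.
Passing tests on synthetic data therefore demonstrate the correctness of
the statistical machinery under the model's assumptions, not instrument-
level performance on real charcoal.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the study at its native
scale: 6 calibration spectra per taxon on the 250-point grid, 199
permutations per validation (99 inside repeated Monte Carlo loops), 20
seeded recovery replicas of 5 archaeological spectra each, and a 200-run
uniformity check of the permutation p-value. NIPALS stops extracting
factors when the residual covariance norm falls below 10⁻¹² of the initial
scale; requesting more factors than the data rank is an error naming the
achievable maximum in direct fits, while cross-validation folds truncate
gracefully (a fold with no extractable factor predicts its training mean).
Ties in factor selection resolve to fewer factors. Zero-variance spectra
(SNV undefined) and zero-variance responses are rejected with the offending
sample named.

## Known limitations

- Six calibration points bound the usable factor count (F ≤ 4) and make
  every quality metric high-variance; the permutation guard is the main
  defence against overfitting, not the r² itself.
- VIP band positions on noisy data are stable to about one grid step
  (≈ 5.6 cm⁻¹); for particular noise realisations the weakest band's
  reported position can drift slightly beyond that, so band lists should be
  read at that resolution.
- The SNV transform couples all wavenumbers through the per-spectrum mean
  and standard deviation, so VIP attributes some importance to
  temperature-insensitive regions; diagnostic bands are ranked maxima, not
  an exclusive support set.
- Calibrations are taxon-specific by construction: predicting archaeological
  spectra with another taxon's model is not prevented by chemistry, only by
  workflow discipline (the objects carry their taxon and group contrasts
  check it).
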