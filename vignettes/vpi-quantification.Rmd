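---
title: "Quantifying vesicle-protein interactions from single-vesicle TIRF data"
author: "vpiq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vesicle-protein interactions from single-vesicle TIRF data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpiq)
```

## The measurement

Membrane vesicles (extracellular vesicles and their extruded mimetics) dock
onto target cells through proteins at the vesicle-membrane interface. A
single-vesicle TIRF assay quantifies this directly: target proteins (for
example ICAM-1 bait for integrin-bearing vesicles) are displayed on a
coverslip at a controlled surface density, fluorescently labelled vesicles
are flowed in, and each stably bound vesicle appears as one
diffraction-limited spot. The observable is therefore a *count*, not a
photometric signal: a spot contributes one vesicle-protein interaction (VPI)
if and only if its brightness clears a threshold, which makes the readout
robust to labelling heterogeneity and dim contaminants.

`vpiq` implements the full quantification chain for such assays together
with a seeded synthetic-data generator, so that every estimator in the
package can be exercised against known ground truth:

1. **simulation** — spatial-Poisson protein fields, vesicle docking under
   adsorption models, pixel-integrated Gaussian PSF rendering with shot
   noise, read noise, camera offset and channel bleed-through, stepwise
   photobleaching traces;
2. **spot analysis** — frame averaging, local-maximum candidate detection,
   sub-pixel 2-D Gaussian refinement, thresholded VPI counting;
3. **calibration** — linear intensity-to-density conversion anchored in the
   optically countable regime;
4. **photobleaching** — changepoint-based step counting for fluorophore
   stoichiometry;
5. **colocalization** — crosstalk unmixing, one-to-one spot matching,
   chance baselines, enrichment and per-class bound fractions;
6. **inference** — weighted nonlinear least squares, bootstrap CIs, AICc
   model selection, parameter-recovery experiments.

## Adsorption models

All equilibrium constants are in nM; vesicle concentrations are accepted in
pM (or particles/ml via `particlesPerMlToPM()`; 2×10⁹ particles/ml ≈ 3.3
pM).

**Simple Langmuir.** Every surface protein is an independent site:

$$N_b = \alpha\,\rho\,\frac{V}{V + K_d},$$

with bound-vesicle density $N_b$ (vesicles/µm²), protein density $\rho$
(molecules/µm²), vesicle concentration $V$, and a capture-efficiency scale
$\alpha \in (0, 1]$. $N_b$ is strictly linear in $\rho$.

**Density-dependent cooperation.** At high density, neighbouring proteins
within a geometric reach $d$ can jointly capture one vesicle. On a Poisson
field the probability that a protein has no neighbour within $d$ is
$e^{-\lambda}$ with $\lambda = \rho \pi d^2$, giving site densities

$$s_1 = \rho\, e^{-\lambda}, \qquad s_2 = \tfrac{1}{2}\rho\,(1 - e^{-\lambda}),$$

(single sites and paired sites; $s_1 + 2 s_2 = \rho$ exactly) and

$$N_b = \alpha\left[s_1 \frac{V}{V + K_{d,1}} + s_2 \frac{V}{V + K_{d,2}}\right].$$

With $K_{d,2} \ll K_{d,1}$ the pair term grows like $\rho^2$ at low density,
producing the super-linear (log-log slope approaching 2) signature that
distinguishes cooperative vesicle capture from simple adsorption. As
$d \to 0$ the model collapses to Langmuir with $K_{d,1}$.

The reach defaults to $d = 0.1$ µm, the contact footprint of a vesicle of
~140 nm diameter. The simulator realizes the same geometry explicitly:
greedy mutual-nearest-neighbour pairing within $d$, with leftover members
of triplets and larger cliques treated as monomeric sites. We note one open
interpretation: a supplementary formulation could count all proteins within
the vesicle footprint instead of pairing them; the super-linearity and the
two-constant structure are common to both, but a fitted $d$ is
interpretation-dependent.

**Hill, inhibition, kinetics.** Vesicle-concentration curves are fitted
with $N = N_{max} V^n / (V^n + K_{1/2}^n)$; inhibitor dose-response with
$N = N_{bg} + (N_0 - N_{bg}) / (1 + (c/\mathrm{IC}_{50})^h)$; association
time courses with $N(t) = N_{eq}(1 - e^{-(k_{on} V + k_{off}) t})$.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `pixelSize` | 0.108 | µm/px | 60× objective on an sCMOS |
| `psfSigma` | 0.13 | µm | visible-wavelength diffraction limit |
| `frames` × `frameInterval` | 10 × 0.1 | s | initial-frame averaging window |
| `photonsPerFluorophore` | 1000 | counts/frame | bright single fluorophore |
| `cameraOffset`, `readNoiseSd` | 100, 2 | counts | sCMOS-like camera |
| reach `d` | 0.1 | µm | vesicle contact footprint |
| `minSeparation` | 3 | px | non-maximum suppression window |
| detection `k` | 5 | × noise sd | 5-sigma candidate threshold |
| `matchRadius` | 0.216 | µm (2 px) | diffraction-limited co-detection |

## What the generator emulates — and what it does not

The generator reproduces the features that drive the estimators: Poisson
point statistics, diffraction-limited overlap (hence the countability
ceiling near ~1 spot/µm²), shot + read noise, stepwise bleaching with
exponential lifetimes, log-normal vesicle brightness (sdlog 0.3, a peaked
intensity histogram with a bright tail), and linear channel mixing applied
to expected photon images before noise.

It deliberately omits lateral diffusion, stage drift, TIRF evanescent-depth
variation, vesicle-size polydispersity beyond the brightness factor, and
non-uniform illumination. Passing tests therefore certify the estimators
against the *modelled* physics; on real data, flat-field and registration
errors add systematic terms the simulation does not probe.

Replicate scatter in binding tables is multiplicative Gaussian with a 10%
CV and 5 technical replicates per level (the typical field-to-field scatter
of repeated TIRF images), at 3 pM vesicles over densities 0.5–40
molecules/µm².

## Numerical and statistical choices

**Detection.** Background is the image median and the noise scale its MAD
(robust to sparse spots). Candidates are local maxima in a
(2·`minSeparation`+1)² window above `k`× noise; equal-valued maxima are
resolved by decreasing peak value, then row, then column. Each candidate is
refined by a 5-parameter Gaussian fit in a 7×7 px window; fits that move
more than 2 px or leave σ ∈ [0.5, 3]×nominal are discarded. Because the fit
window cannot straddle the border, densities are reported over the interior
("effective") area. Fields of 25.92 µm (240 px) are used throughout the
test-suite simulations — large enough for counting statistics, small enough
to keep the suite fast.

**Calibration.** Built from ladder levels at ρ ≤ 1 spot/µm² (configurable
cut), regressing total intensity on *measured* spot density with
inverse-variance weights, intercept free. For ladder counting a tighter
2 px suppression window is used: at 3 px a noticeable fraction of genuinely
resolvable neighbours is merged already at ρ ≈ 0.3/µm², which would bias
the slope upward by ~5%. Round-trip accuracy is assessed against the
*realized* density of the simulated field (points/area), since the Poisson
fluctuation of the molecule count at low density is a property of the
field, not of the conversion.

**Step counting.** Binary segmentation with minimum segment length 2 and a
BIC-style acceptance gain of $2\hat\sigma^2\log n$ per changepoint, with
$\hat\sigma$ from the MAD of first differences. Steps are downward level
changes exceeding half the median absolute change; upward changes flag the
trace "non-bleaching" (blinking is not modelled). Simulated traces use a
bleach rate of 0.2 /s over 300 frames of 100 ms at step SNR 5; at this rate
~6% of three-fluorophore traces bleach two fluorophores within two frames
and are intrinsically merged, which bounds the per-class accuracy.

**Weighting in fits.** Replicate scatter is multiplicative, so per-level
variances follow a constant-CV model. The default weights are
quasi-likelihood style — $n_l / (\widehat{cv}\cdot\mu_l(\theta))^2$,
recomputed from the model prediction at every iteration — because
five-replicate sample variances are too noisy to use raw (a level whose
sample variance is accidentally tiny would dominate the fit), and weighting
by observed means biases relative least squares downward. Raw
inverse-variance weighting remains available (`weights = "replicate-sd"`).

**Fixed versus free parameters.** On a density-axis curve at a single
vesicle concentration only the products $\alpha V/(V + K_d)$ are
identifiable, so `fitModel()` fixes α = 1 by default (`freeAlpha` to
override) and fixes the reach $d$ at its known geometric value
(`fitD` to free it). Equilibrium constants are optimized in log₁₀ space
within [10⁻⁴, 10⁴] nM, with ≥5 seeded starts.

A caution on the weak constant: under the default study conditions the
monomer term of the cooperative model contributes only ~8% of the signal at
the lowest density (occupancy $V/(V+K_{d,1}) \approx 2\times10^{-5}$ at
3 pM and 130 nM). The model is linear in the two site occupancies, so the
generalized-least-squares covariance gives the best achievable precision of
any unbiased estimator directly: relative SE ≈ 0.59 for the monomer
occupancy, i.e. about a 76% chance of landing within a factor of two of the
true $K_{d,1}$ — whereas $K_{d,2}$ is recovered to ~±0.01 dex. The
recovery experiments in the test suite perform at this information limit;
tightening $K_{d,1}$ requires more replicates, lower noise, or additional
densities below 0.5 molecules/µm², not a different estimator.

**Model selection.** AICc (k = parameters + 1) on replicate-level means; a
model with more parameters must improve AICc by more than 2, ties go to the
smaller model, and candidates with fewer distinct x values than parameters
+ 2 are excluded by an identifiability guard.

**Unmixing.** Observed channels obey $obs = B^\top true$; correction
inverts $B$ per pixel after removing the camera offset. Negative results
are floored at 0 by default (the physical convention); flooring rectifies
noise, so residual-bleed photometry uses `floor = FALSE` and least-squares
amplitudes at known spot positions (`spotAmplitudeAt()`).

**Degenerate inputs.** Constant or saturated images, calibrations with
fewer than three levels or non-positive slope, traces shorter than 20
frames, single-class intensity comparisons, non-increasing time vectors and
negative rates all raise errors naming the offending argument; monotone
*increasing* dose-response data are flagged "non-inhibitory" rather than
fitted.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(fieldSize = 25.92, frames = 10L,
                        photonsPerFluorophore = 300, seed = 42L)
surf <- simulateProteinSurface(density = 0.5, cfg)
model <- cooperativeModel(kd1 = 130, kd2 = 0.09, d = 0.1)
vesicles <- simulateVesicleBinding(surf, model, conc = 3, cfg)
stack <- renderImageStack(list(vesicle = vesicles), cfg)
img <- averageInitialFrames(stack, 10L, "vesicle")
countVPI(img, cfg@pixelSize, cfg@psfSigma, vpiThreshold = 1)$density

curve <- simulateBindingCurve("nk-like-cooperative", seed = 42L)
fit <- fitModel(curve, "cooperative", nBoot = 200L, seed = 42L)
fit
selectModel(curve)
```

## Known limitations

* The cooperation model collapses triplets and larger clusters to one pair
  plus singles — exactly two site classes, by design.
* The capture-efficiency scale α is a free normalization; absolute
  comparisons across vesicle preparations require a shared α calibration.
* No channel registration is implemented; simulated channels are
  pre-registered, and a rigid-offset registration hook is left to future
  work.
* Chance colocalization is reported alongside measured fractions, never
  subtracted, so fractions remain comparable with uncorrected literature
  values.
* Pixel-correlation colocalization metrics (Pearson/Manders) are out of
  scope: the assay counts spots, not pixels.
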