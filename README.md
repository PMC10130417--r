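# vpiq — quantitative single-vesicle imaging of vesicle–protein interactions

Membrane vesicles (extracellular vesicles and extruded cell-derived
mimetics) dock onto target cells through proteins at the vesicle–membrane
interface. In a single-vesicle TIRF assay, target proteins are displayed on
a coverslip at a controlled surface density, fluorescently labelled
vesicles are added, and every stably bound vesicle appears as one
diffraction-limited spot; a spot is registered as one vesicle–protein
interaction (VPI) if and only if its brightness exceeds a threshold, so
the readout is a count, robust to labelling heterogeneity.

`vpiq` is for experimentalists and method developers who run (or simulate)
such assays. It implements the full quantification chain and a seeded
synthetic-data generator with known ground truth:

* **Simulation** — spatial-Poisson protein fields (0.01–40 molecules/µm²,
  optional dimer fraction), vesicle docking under adsorption models,
  pixel-integrated Gaussian PSF rendering with shot/read noise and
  inter-channel bleed-through, stepwise photobleaching traces, binding
  time courses, on-disk fixture bundles (TIFF + CSV + JSON manifest).
* **Spot analysis** — initial-frame averaging, local-maximum detection with
  sub-pixel 2-D Gaussian refinement, spot densities, total-field
  intensities, thresholded VPI counting.
* **Calibration** — linear intensity-to-density conversion built in the
  countable regime (ρ ≤ 1 spot/µm²) and extrapolated beyond the
  diffraction ceiling, with self-quenching diagnostics.
* **Photobleaching** — binary-segmentation step counting, fluorophore
  stoichiometry, brightness-based multimer tests.
* **Colocalization** — crosstalk estimation from pure species, linear
  unmixing, one-to-one spot matching with analytic chance baselines,
  fold-enrichment, per-class vesicle-bound fractions, ratiometric molar
  ratios.
* **Inference** — weighted nonlinear least squares with multi-start log-space
  optimization, bootstrap CIs, AICc model selection, parameter-recovery
  experiments (table-level and full image-level).

## The models

With protein density ρ (molecules/µm²) and vesicle concentration V (pM;
`particlesPerMlToPM()` converts particle counts — 2×10⁹ particles/ml ≈ 3.3
pM):

* simple Langmuir adsorption: `N_b = α ρ V/(V + K_d)` — linear in ρ;
* density-dependent cooperation: isolated proteins (density
  `s1 = ρ exp(−ρπd²)`) bind with `K_d1`, proteins paired within a reach d
  (density `s2 = ρ(1 − exp(−ρπd²))/2`) form high-affinity sites with
  `K_d2 ≪ K_d1`:
  `N_b = α [s1 V/(V+K_d1) + s2 V/(V+K_d2)]` — super-linear in ρ;
* Hill (`N_max Vⁿ/(Vⁿ + K_half ⁿ)`), sigmoidal IC50 inhibition, and
  pseudo-first-order kinetics for concentration, dose and time axes.

## Worked example

```r
library(vpiq)

cfg <- simulationConfig(fieldSize = 25.92, frames = 10L,
                        photonsPerFluorophore = 300, seed = 42L)
surf <- simulateProteinSurface(density = 10, cfg)
model <- cooperativeModel(kd1 = 130, kd2 = 0.09, d = 0.1)
vesicles <- simulateVesicleBinding(surf, model, conc = 3, cfg)
vesicles
#> VesicleField: 33 bound vesicles ( 33 on paired sites )

stack <- renderImageStack(list(vesicle = vesicles), cfg)
img <- averageInitialFrames(stack, 10L, "vesicle")
countVPI(img, cfg@pixelSize, cfg@psfSigma, vpiThreshold = 1)$count
#> [1] 32
```

At 10 molecules/µm² and 3 pM vesicles, essentially all captures happen on
paired sites — the cooperative regime — and 32 of the 33 bound vesicles
are recovered by detection (one sits too close to the field border to fit).
Fitting a replicated binding curve recovers the constants and selects the
generating model:

```r
curve <- simulateBindingCurve("nk-like-cooperative", seed = 42L)
fit <- fitModel(curve, "cooperative", nBoot = 200L, seed = 42L)
fit
#> FitResult [ cooperative ] converged
#>   kd1 = 277.8, kd2 = 0.08735
#>   kd1 95% CI [116.2, 10000]
#>   kd2 95% CI [0.08405, 0.09111]
#>   RSS 5.677 | AICc 12.53

selectModel(curve)
#> ModelComparison: selected = cooperative
#>          kind nPar         rss     aicc converged    dAicc
#> 1    langmuir    1 1497.899890 44.56136      TRUE 32.02746
#> 2 cooperative    2    5.677254 12.53390      TRUE  0.00000
```

The paired-site constant `kd2` is pinned to ±4%, while `kd1` — the weak
monomer constant, carrying ~8% of the signal at the lowest density — is
recovered only to within a factor of ~2, with an honest bootstrap CI to
match; see the vignette (`vignettes/vpi-quantification.Rmd`) for the
information-limit analysis.

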