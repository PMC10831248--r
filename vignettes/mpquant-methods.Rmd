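---
title: "Methods: quantifying membrane-protein interactions by peptidisc mass photometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying membrane-protein interactions by peptidisc mass photometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpquant)
```

## The measurement and its model

Mass photometry records single particles landing on a glass–buffer
interface; each landing event yields a dimensionless interferometric
scattering contrast proportional to particle mass. `mpquant` starts from
per-event tables (contrast and/or calibrated mass in kDa) and models the
downstream analysis for peptidisc-reconstituted membrane proteins:

1. **Contrast → mass.** Ordinary least squares through calibrant points
   `(mean contrast, known mass)`, `mass = slope·contrast + intercept`.
   Calibrant runs recorded before and after an experiment are pooled into
   one unweighted fit; the per-run slope difference is available from
   `calibration_drift()` for inspection but never acted on, because a
   correction scheme would need a drift model the data cannot identify.
2. **Mass spectrum.** The event masses are smoothed with a Gaussian
   kernel of width σ = 5 kDa into a kernel-density estimate on a uniform
   1 kDa grid spanning the data range ± 5 kernel widths. The density is
   normalized to unit trapezoidal area; event counts are kept separately
   since every downstream quantity is an area *ratio*.
3. **Two-component decomposition.** A measurement of receptor R with
   ligand L is modelled as two Gaussians: free receptor centered within
   ± 1 kDa of the experimentally determined receptor mass, and complex
   centered within ± 1 kDa of receptor + ligand *sequence* mass. Both
   share one fixed width σ\_fixed taken from a free single-Gaussian fit
   of the zero-ligand measurement of the same series (typically
   10–15 kDa; values outside that range trigger a warning). Only the two
   non-negative areas and the box-constrained centers are free. The bound
   fraction is `area_complex / (area_receptor + area_complex)`. The free
   ligand itself (≈ 30 kDa) sits below the instrument detection floor and
   contributes no component.
4. **Baseline and depletion correction.** The apparent complex fraction
   of the zero-ligand measurement — the receptor peak's right shoulder
   leaking into the complex box — is subtracted from every condition.
   Free ligand is then `L_free = L_titrated − f·R_effective`, where
   `R_effective = purity · R_nominal` and purity is the receptor Gaussian
   area over the total distribution area of the ligand-free sample.
   Points with `L_free < 1 nM` are excluded: too few events sit under
   those peaks for a reliable fraction.
5. **K_D.** Percent bound versus free ligand is fitted, unweighted, to
   the Hill form with coefficient fixed at 1,
   `A + (B − A)·L/(K_D + L)` with `0 ≤ A, B ≤ 100` and `K_D > 0`.
   Replicates are combined by pooling all included points into one joint
   fit; per-replicate fits and a log-binned mean ± s.d. display summary
   are reported alongside.

Separately, the package closes the peptidisc mass balance: a phosphate
standard curve (linear regression of absorbance at 820 nm on nanomoles of
phosphate, duplicates averaged first) yields lipids per disc;
`disc_composition()` then splits the measured particle mass into protein,
lipid (`n_lipids × 0.8 kDa`, the average phospholipid) and scaffold mass,
and converts the latter into a peptide count at 4.5 kDa per scaffold
peptide. `assign_stoichiometry()` explains the mass of a multi-component
species by exhaustive enumeration of integer combinations.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `kernel_sigma` | 5 | kDa | standard spectral smoothing for these data; well below instrument width |
| `grid_spacing` | 1 | kDa | sub-kernel resolution with bounded memory; must be ≤ σ/2 |
| `mu_tolerance` | 1 | kDa | allowed slack on known centers; applied independently to both boxes |
| `sigma_fixed` | from zero-ligand fit | kDa | shared component width; warning outside 10–15 |
| `min_free` | 1 | nM | free-ligand floor below which fractions are unreliable |
| Hill bounds | 0–100 | % | physical range of a bound fraction |
| `mass_sigma` | 12 | kDa | mid-range of typical per-event widths for ~200 kDa discs |
| `detection_limit` | 40 | kDa | hides a ~30 kDa free ligand, passes all receptor species |
| `lipid_unit_mass` | 0.8 | kDa | average phospholipid mass |
| `peptide_unit_mass` | 4.5 | kDa | published scaffold-peptide mass; both reference disc compositions reproduce under it |
| `rel_tolerance` | 0.05 | – | accepts the 420→426 (1.4%) and 670→696 (3.7%) assignments, rejects gross mismatches |

## The synthetic-data generator

`simulate_sample()` draws events from a stated world: species sampled
with probability proportional to weight, per-event mass
`Normal(true mass, mass_sigma)`, events below the detection floor
discarded, contrast derived *deterministically* from the drawn mass
through the linear instrument model. `simulate_titration()` sets the
per-condition bound fraction to
`f* = A + (B − A)·f_eq`, with `f_eq` the exact depletion-aware 1:1
mass-action occupancy (`equilibrium_fraction_bound()`, the closed-form
root of the binding quadratic), and includes free-ligand events in
proportion to the free concentration.

Deliberate simplifications, and therefore what a green test does *not*
establish:

* No optics: no movie synthesis, focus drift, or landing-position
  effects; per-event mass error is a single Gaussian width, while real
  contrast noise is mass-dependent.
* Contrast noise lives in mass space only, keeping calibration
  round-trips exact; real calibrations drift between runs.
* The default dilution factor 11 (2 µL of binding mixture into 20 µL of
  buffer) thins the expected event count only; equilibrium fractions are
  assumed to survive dilution on the measurement timescale, which holds
  for off-rates of minutes or slower. Fast-off systems would partially
  re-equilibrate and the simulator does not emulate that.
* Landing counts are Poisson (fixed-count override for deterministic
  tests); masses are i.i.d., with no surface crowding or coincidence.
* Seeds are mandatory everywhere; identical config + seed gives
  byte-identical tables, and the caller's RNG stream is never touched.

## Numerical choices

* **Fit target.** The two-Gaussian model is fitted to the unit-area KDE
  sampled on its grid, with the model convolved with the same kernel
  (component curve width `sqrt(sigma_fixed² + kernel_sigma²)`), making
  the objective binning-free and reproducible; whether one fits count
  histograms or smoothed curves is otherwise an arbitrary choice. A raw
  5 kDa-bin histogram mode (`method = "histogram"`) is provided and
  agrees within sampling noise.
* **Optimizer.** Box-constrained L-BFGS-B with `factr = 1e2` for the
  decomposition objective — at default tolerance the optimizer can stop
  visibly short of the constrained optimum on this mixed-scale problem
  (kDa centers next to unit areas), which a nested grid-search oracle in
  the test suite detects. Amplitudes are initialized from KDE heights at
  the fixed centers; K_D from the geometric mean of included free-ligand
  values, A from 0, B from the largest observed fraction. All
  initialization is deterministic; there are no random restarts.
* **Bound reporting.** A parameter that stops on a box bound with the
  objective still decreasing outward is *flagged* (warning plus a
  `flagged_bounds` field), never silently clipped; a gradient below
  numerical noise (relative to both gradient and objective scale) is not
  flagged, so an optimum that genuinely sits on a bound — e.g. B = 100%
  for a saturating noiseless titration — passes quietly. Component areas
  pinned at zero are a legitimate boundary solution and are likewise not
  flagged.
* **Baseline not clamped.** Corrected fractions may go slightly negative
  for non-baseline conditions; they are retained so the Hill baseline A
  can absorb residual offset — clamping would bias K_D upward. Only the
  Hill fit's 0–100% box enforces physical range.
* **Degenerate inputs.** Fewer than 50 events refuse to fit; a sample
  entirely below the detection limit returns an empty table with a
  warning; identical calibrant contrasts, single-level phosphate
  standards, and all-excluded titrations raise explicit errors.
  `peak_fwhm()` errors when the half height is not crossed on the grid.
* **Rounding and ties.** Scaffold peptide counts use half-up rounding to
  the nearest integer (counts are reported as integers). Stoichiometry
  ties break by smaller total copy number, then lexicographically by
  component order — fully deterministic, verified against a brute-force
  oracle.

## Design decisions that were genuinely open

* The σ used for the shared width is *deconvolved* from the zero-ligand
  KDE fit (`sqrt(σ_curve² − kernel²)`), so the reported width is on the
  raw-histogram scale where the 10–15 kDa expectation is defined, then
  re-convolved inside the model. This keeps one width definition across
  both fit modes.
* The ± 1 kDa center tolerance is applied as two independent box
  constraints (receptor center and complex center), not as a constraint
  on the ligand-mass offset; with both boxes 1 kDa wide the difference is
  immaterial for well-separated peaks, and independent boxes keep the
  optimization separable.
* Pooled K_D fitting uses all included points of all replicates jointly;
  per-replicate fits are also reported. The mean ± s.d. display bins the
  free-ligand axis in log-spaced bins with geometric centers, because
  free ligand — unlike titrated ligand — differs between replicates.
* The expected fraction of events classified to the heavier species of a
  70:30 mixture at 12 kDa width is *not* 0.30: nearest-mass
  classification leaks ~11% of each population across the midpoint, so
  the test suite asserts the analytically corrected expectation (≈ 0.34)
  rather than the naive weight.

## Limitations

* Equilibrium-only: no on/off-rate or ATPase-activity modelling; K_D is
  meaningful only if the mixture is at equilibrium when measured.
* The method needs the receptor and complex masses separated by roughly
  twice the per-event width; ~30 kDa ligands on ~200 kDa receptors
  (Δμ ≈ 2.45 σ) are near the practical floor, and small-molecule binding
  is out of reach.
* The Hill coefficient is fixed at 1; cooperative systems would need a
  different isotherm.
* Purity enters as a single scalar on receptor concentration; ligand
  concentration errors and active-fraction effects are not modelled and
  bias K_D directly, as in any depletion-corrected titration.
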