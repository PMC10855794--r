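# lensepr

Spin-label EPR analysis of alpha-crystallin binding to cholesterol-containing
model human lens-lipid membranes.

Alpha-crystallin (the lens chaperone, as alphaA, alphaB, or their 3:1
complex alphaAB) binds the lens fiber-cell membrane; cholesterol and the
cholesterol bilayer domains (CBDs) it forms at high content modulate that
binding, which matters for cataract formation. The binding is measured with
the cholestane spin label (CSL), a cholesterol-analog nitroxide embedded at
1 mol% in small unilamellar vesicles: continuous-wave EPR records the first
derivative of absorption versus magnetic field, and protein bound at the
membrane surface immobilizes nearby labels, draining amplitude from the
sharp low-field hyperfine line.

`lensepr` implements the full measurement chain, plus a synthetic-spectrum
generator with known ground truth so every stage is testable without
instrument data:

* **Spectra.** Three-line fluid-phase (37 °C) and rigid-limit (−165 °C)
  first-derivative spectra; two-component unbound + bound mixtures;
  seeded titration datasets.
* **Features.** Baseline correction; peak-to-peak heights of the low-field
  and central lines and the mobility parameter h+/h0; maximum splitting
  (order); rigid-limit 2Az (hydrophobicity: larger 2Az = more polar, less
  hydrophobic).
* **Binding.** Percent of labels affected,
  `(U0 − (U0 + B0)) / U0 × 100`, from spin-count-normalized low-field
  amplitudes; the spherical-vesicle outer-leaflet correction
  `Ro² / (Ro² + Ri²)` (≈ 100/54 at Rh = 56 nm); the one-site law
  `MSO(C) = MMSO · Ka · C / (1 + Ka · C)` fitted by bounded multi-start
  nonlinear least squares, with a zero-binding convention for
  cholesterol-saturated membranes.
* **Composition.** Mixing ratio ↔ mol% cholesterol (`100 r / (1 + r)`),
  the composition-weighted CBD onset, and domain labels
  (no saturation / LCD / LCD+CBD).
* **Report.** Replicate aggregation (mean ± SD, n ≥ 3), Student's t-tests
  (Welch or pooled, p ≤ 0.05), and deterministic report tables for the full
  synthetic study via `run_pipeline()`.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fits, `autoplot()` on spectra and fits, and a
thin command-line wrapper in `inst/cli/lensepr.R`
(`simulate | features | bind | cbd | report`).

## Worked example

Simulate a titration whose truth is MMSO = 60%, Ka = 0.2 /µM (nine
concentrations 0–60 µM, three replicates, 2-percentage-point MSO noise),
then run the measurement chain and fit:

```r
library(lensepr)

ds <- simulate_titration(
  binding_truth(mmso_pct = 60, ka_per_uM = 0.2),
  titration_design(seed = 42),
  vesicle_geometry(rh_nm = 56)
)
ana <- analyze_titration(ds)
ana
#> <titration_analysis> 27 points, 3 replicate(s)
#> <binding_fit> one-site ligand binding
#>   MMSO = 58.9 +/- 1.1 %   Ka = 0.2127 +/- 0.017 /uM
#>   R^2 = 0.984, n = 27, converged = TRUE
```

The fit recovers the simulated plateau (58.9% vs the true 60%) and affinity
(0.213 vs 0.2 /µM) from the spectra alone. The per-sample chain is visible
in `tidy(ana)`: the normalized low-field amplitude falls with concentration,
giving the percent of labels affected and, after the outer-leaflet
correction, MSO:

```r
tidy(ana)[2:3, ]
#>   conc_uM replicate u0b0_amp affected_pct mso_pct
#> 1     2.5         1   0.1000         10.0    18.6
#> 2     5           1   0.0930         16.3    30.3
autoplot(ana)   # points + fitted one-site curve
```

Membrane physical properties come from the same spectra:

```r
sp <- simulate_fluid_spectrum(fluid_params(), field_grid())
locate_lines(sp)[, c("mobility", "max_splitting_G")]
#>   mobility max_splitting_G
#> 1   0.6944              33
rigid_limit_2az(simulate_rigid_spectrum(rigid_params(Az_G = 33.5)))$two_Az_G
#> [1] 70.00005
```

And the composition calculus reproduces the printed membrane numbers:

```r
round(100 * outer_leaflet_fraction(rh_nm = 56, bilayer_thickness_nm = 4))
#> [1] 54        # % of labels on the outer leaflet -> the 100/54 correction
cbd_onset(membrane_composition())
#> [1] 45.81     # ~46 mol% cholesterol: CBD onset of the lens-lipid membrane
mixing_ratio_to_molpct(c(0.5, 1.5))
#> [1] 33.33333 60.00000
```

`run_pipeline(default_study_config(seed = 1))` runs the whole synthetic
study (3 proteins × 3 mixing ratios) and returns binding, mobility,
maximum-splitting, hydrophobicity, domain and significance tables;
`write_report()` writes them as TSV with seed and configuration hash in the
header. Re-running with the same seed reproduces the tables byte for byte.

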