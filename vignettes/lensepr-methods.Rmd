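---
title: "Methods: spin-label EPR quantification of alpha-crystallin membrane binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin-label EPR quantification of alpha-crystallin membrane binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lensepr)
```

## The measurement problem

Alpha-crystallin — the dominant chaperone protein of the eye lens, present as
alphaA (alphaA-crystallin), alphaB, and their 3:1 heteromeric complex alphaAB
— binds to the lens fiber-cell membrane, and that binding is thought to be a
step in cataract development. The binding can be quantified with a
cholesterol-analog nitroxide probe, the cholestane spin label (CSL), embedded
at 1 mol% in small unilamellar vesicles (SUVs) made from a model human
lens-lipid mixture (66% sphingomyelin, 11% POPC, 15% POPE, 8% POPS) with
added cholesterol. Continuous-wave EPR records the first derivative of
absorption versus magnetic field. CSL sits with its reporter group near the
membrane headgroups, so its three-line nitroxide spectrum reports what
protein binding does at the membrane surface:

* **Occupancy.** Protein that binds at the surface immobilizes nearby
  labels, draining amplitude from the sharp low-field line. Comparing a
  protein-added sample with the protein-free control gives the percent of
  labels affected and, after a geometric correction, the percentage of
  membrane surface occupied (MSO). Titrating protein and fitting a one-site
  binding law gives the plateau occupancy (MMSO) and an association constant
  (Ka).
* **Mobility.** The ratio of the low-field to central peak-to-peak heights
  (h+/h0) falls as the headgroup region becomes less mobile.
* **Order.** The field distance from the low-field positive extremum to the
  high-field negative extremum ("maximum splitting") grows with headgroup
  order.
* **Hydrophobicity.** In frozen samples (about -165 degC) the outer-extrema
  separation 2Az measures the polarity of the probe environment; a larger
  2Az means a more polar, less hydrophobic surface.

No raw spectra are distributed with the source study, so this package pairs
the analysis chain with a synthetic-spectrum generator carrying known ground
truth. Every stage is therefore testable end to end: simulate spectra whose
true occupancy is known, run the measurement chain, and compare.

## The synthetic spectrum model

Each hyperfine line (mI = +1, 0, -1, at `center_G - mI * hyperfine_G`) is
the field derivative of a unit-area pseudo-Voigt absorption profile,
parameterized by its peak-to-peak derivative width. Closed-form anchors used
by the tests: the derivative extrema sit exactly half a peak-to-peak width
either side of the line center, and the peak amplitude scales as
1/width^2 at fixed integrated intensity.

The study-default lineshape is pure Gaussian (`shape_mix = 0`) on a
3250-3430 G window of 4096 points. The Gaussian choice is deliberate: the
percent-affected calculation rests on spin-count (double-integral)
normalization, and on any finite sweep window the long tails of a Lorentzian
component leak of order a percent of their area past the edges, which would
make the numeric double integral depend on linewidth. With Gaussian lines on
this window the truncated tail mass is below 1e-12 and the double integral
is conserved under any width or bound-fraction change to better than 1e-9
relative — which is also what the conservation tests assert. Lorentzian
blends (`shape_mix > 0`) remain available; position-based quantities are
unaffected by the choice.

A protein-added sample is a two-component mixture: `(1 - f)` unbound plus
`f` bound at equal total integrated intensity. The bound (immobilized)
population reuses the unbound parameters with per-line width scales of
(5, 2, 5) by default. Two requirements fix those numbers:

* The percent-affected formula reads the amplitude loss of the sharp
  low-field line and implicitly assumes the bound population contributes
  nothing there. For derivative-Lorentzian lines the bound leakage at the
  unbound extremum is `beta(k) = (16/9) k / (1/3 + k^2)^2` of the unbound
  amplitude (similar for Gaussian); at the literature-style scalar scale
  k = 3 this is 6%, which corrupts recovered MSO by about 3 percentage
  points at high occupancy. At k = 5 the leakage is 1.4% and the recovery
  error stays below 0.8 MSO points over the whole design — the
  oracle-equivalence tests assert under 1 point.
* A uniform scalar scale would leave h+/h0 exactly invariant to the bound
  fraction (both lines shrink by the same factor), contradicting the
  observed mobility decrease with binding. Broadening the outer lines more
  than the central one (5 vs 2) is the anisotropic-immobilization case and
  produces the monotone mobility decrease the property tests check.

The rigid-limit generator is deliberately minimal: two outer derivative
features at `center +/- Az` plus a broad central hump, not a powder-pattern
integral, because only the outer-extrema separation is consumed downstream.
Its documented separation law is `2 Az + outer_width`.

## Titration simulation and the noise model

A titration follows the experimental design: protein at 0 to 60 uM against
11.4 mM lipid plus cholesterol, at least three independently prepared
replicates. True occupancy follows `MSO(C) = MMSO * Ka * C / (1 + Ka * C)`;
the bound fraction passed to the spectrum simulator is
`MSO(C) * outer_fraction / 100`.

Noise enters in two ways, both chosen once as plausible bench-scale scatter:

* **Per-point MSO noise** (`noise_sd_mso`, default 2 percentage points):
  Gaussian perturbation of the occupancy of each C > 0 point; the perturbed
  value sets the component amplitudes of that trace, so the noise reaches
  the spectrum through the amplitudes, consistently between control and
  sample. The C = 0 control is exact, as the analysis defines each
  replicate's own control as its amplitude reference.
* **Replicate width jitter** (`width_jitter_rel`, default 0.003, lognormal),
  plus a 0.08 G jitter on the rigid-limit Az in the full study: independent
  sample preparations differ slightly in lineshape. The jitter is shared
  between a replicate's control and protein spectra, so it cancels in the
  amplitude ratio and does not inflate MSO noise, but it gives replicate
  SDs and t-tests realistic, non-degenerate inputs.

What the generator does **not** emulate: slow-motional (stochastic
Liouville) lineshapes, field-modulation distortion, microwave saturation,
baseline drift beyond linear, or correlated noise. Passing tests therefore
demonstrate that the analysis chain is correct for well-behaved
motional-narrowing spectra with known truth — not that it is robust to every
instrumental artifact of real data.

## Feature extraction

Spectra are baseline-corrected by a straight line fitted to the outer 5% of
points on each edge (falling back, with a warning, to a constant offset if
the edges appear to contain signal). Lines are identified by
prominence-ranked local-extremum search with a minimum-separation constraint
(default 6 G, about half the hyperfine splitting; ties resolved toward lower
field), and every reported extremum is refined by 3-point parabolic
interpolation — maximum-splitting differences of interest are on the 1 G
scale, well above the interpolation residual (~1e-4 G) but close to a bare
grid step. The extraction never assumes the generative lineshape; accuracy
against the analytic extrema of the generator (positions within one grid
step, heights within 2%) is asserted on the 4096-point grid. Optional
Savitzky-Golay smoothing (off by default) is available and must be applied
identically to control and sample.

Amplitudes entering the percent-affected ratio are normalized by the
spectrum's double integral. The lipid and spin-label content is fixed across
a titration, so the double integral is proportional to the spin count; this
makes control and sample amplitudes comparable and the whole chain invariant
to uniform intensity rescaling (spectrometer gain). Whether the source
study normalized amplitudes this way is not stated; spin-count normalization
is recorded here as the package's own, defensible choice.

## From amplitudes to binding parameters

The percent of labels affected is `(U0 - (U0 + B0)) / U0 * 100`; small
negative values (noise) are clamped to zero with a warning, never silently.
Only outer-leaflet labels can be reached by protein, so MSO divides by the
outer-leaflet fraction `Ro^2 / (Ro^2 + Ri^2)` of a spherical SUV — 0.537
(about 54%, i.e. the familiar 100/54 correction) at the measured
hydrodynamic radius of 56 nm with the default 4.0 nm bilayer thickness. The
4.0 nm default is the thickness consistent with the published 54% at 56 nm;
it is configurable.

The one-site fit uses bounded Levenberg-Marquardt (MMSO in [0, 100],
Ka >= 0) with multi-start Ka initialization spanning 1e-3 to 10 per uM,
reporting asymptotic standard errors and R^2. Ka is defined in 1/uM as the
association constant of `MSO = MMSO * Ka * C / (1 + Ka * C)` (the
reciprocal of the dissociation constant of the equivalent Kd form).
Zero-binding convention: when the mean response sits at or below the noise
floor (default 2 percentage points) the saturable model is unidentifiable
and the fit reports MMSO = 0, Ka = 0, converged — the convention used for
cholesterol-saturated membranes. The mean-based trigger (rather than
all-points-below) is deliberate: with 2-point noise clamped at zero, a
true-zero titration has mean response well under 1 point while single
points routinely poke above 2, and the smallest genuine plateau in the
study design (12 points) keeps a wide margin above the floor.

Fits are pooled over replicates (points keep their replicate id), matching
the error-bar-on-points presentation of titration figures; the report layer
additionally fits each replicate separately so that MMSO and Ka can be
summarized as mean +/- SD over at least three independent series and
compared by t-test, as the experimental convention requires.

## Composition calculus

Cholesterol content converts between the mixing ratio r (mol cholesterol
per mol lipid) and mol% as `100 r / (1 + r)`: ratios 0, 0.5, 1.5 are 0, 33,
60 mol%. Cholesterol bilayer domains (CBDs) begin to form at the
composition-weighted sum of the single-lipid onsets (SM 48, POPS 46,
POPC 50, POPE 33 mol%); for the lens-lipid composition this is 45.81, about
46 mol%. Reported values are exact with presentation rounding half away
from zero. Domain labels use a strict inequality for CBDs ("above" the
onset) and a configurable saturation boundary for the lipid-cholesterol
domain (LCD), defaulting to 33 mol% — the content at which the lens-lipid
membrane is observed saturated; that boundary is a documented heuristic,
not a fitted quantity.

## Statistics and the report

Replicates are summarized as mean and sample SD (n - 1) with a warning
below three. Significance uses a two-tailed two-sample Student's t-test,
Welch by default with a pooled-variance option, at p <= 0.05 with no
multiple-testing adjustment (a Holm-style correction can be applied by the
user; the report deliberately mirrors the unadjusted convention).
"Overall change with protein" is operationalized as highest-concentration
versus protein-free comparison per condition — an interpretation, recorded
in the report. Degenerate zero-variance comparisons define t = 0, p = 1 for
equal means.

`run_pipeline()` ties everything together for the default synthetic study:
3 proteins x 3 mixing ratios, 9 concentrations, 3 replicates, 4096-point
spectra (about 250 fluid plus 36 rigid traces; roughly 7 s on one core).
The ground-truth table encodes the qualitative structure of the
experimental findings — at mixing ratio 0, MMSO of alphaA (60) above
alphaB (42) and alphaAB (43) while Ka of alphaA (0.12/uM) is below alphaB
(0.25) and alphaAB (0.24); at ratio 0.5 the plateaus drop by roughly 40%,
71% and 61% with Ka near 0.3/uM; at ratio 1.5 binding vanishes. The
magnitudes are the package's own plausible choices (the binding figures of
the source study are not machine-readable); the orderings are the point,
and the acceptance-style tests assert them, not the magnitudes. Reports are
deterministic: the same seed and configuration reproduce every table byte
for byte, and each TSV carries the seed and a configuration hash in `#`
header lines.

## Known limitations

* The lineshape is a motional-narrowing caricature; no slow-motion or
  powder simulation, so 2Az is meaningful only through the generator's
  documented separation law.
* The percent-affected estimator carries a small negative bias (bound-line
  leakage, under 1 MSO point across the design); a deconvolution-based
  estimator would remove it at the cost of assuming a lineshape.
* Order parameters (S) from A-parallel/A-perpendicular are out of scope, as
  is any thermodynamic phase-diagram or raft prediction; domain labels are
  a bookkeeping of printed thresholds.
* DLS radii are inputs, never computed: the vesicle geometry module starts
  from a measured hydrodynamic radius.
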