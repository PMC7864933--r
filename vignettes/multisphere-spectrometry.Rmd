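---
title: "Multi-directional multi-sphere photoneutron spectrometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-directional multi-sphere photoneutron spectrometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnspec)
```

## The measurement problem

High-energy (≥ 10 MV) X-ray radiotherapy beams produce photoneutrons by
(γ,n) reactions in the accelerator head. Estimating the neutron dose a
patient receives requires the neutron *spectrum*, because the radiation
weighting of neutrons varies strongly with energy. A passive multi-sphere
(Bonner-type) spectrometer measures it indirectly: a thermal-neutron
detector is read out inside a series of polyethylene moderators of
increasing diameter. Small moderators respond mostly to slow neutrons,
large ones shift their sensitivity to fast neutrons, so the vector of
readings encodes the spectrum.

The instrument modelled here is multi-directional: six detectors sit on the
six sides (A–F) of a small polyethylene cube, which is exposed bare and at
the center of eight polyethylene spheres (2–12 inch diameter, cadmium
covered). One measurement location therefore yields 6 sides × 9
configurations = 54 readings, from which six directional spectra and their
mean are unfolded.

## Forward model

Discretized on an energy-group grid, the reading of configuration $i$ is

$$A_i = \sum_g R_{i,g}\,\varphi_g, \qquad A = R\,\varphi ,$$

with $R_{i,g}$ the response of configuration $i$ to unit fluence in group
$g$ and $\varphi_g$ the *group fluence* — the integral of the fluence
density over the group's energy bin. This discretization of the underlying
Fredholm integral equation of the first kind is implemented by `fold()`,
and all totals in the package are plain sums over groups.

Two grids matter:

* the **output grid** (`build_output_grid()`): the 25 representative
  energies, 1.03e-9 to 10.3 MeV, on which unfolded spectra are reported;
* the **training grid** (`build_training_grid()`): 60 geometrically spaced
  groups from 1e-9 to 630 MeV on which synthetic spectra and responses are
  generated.

Group *edges* are never published alongside representative energies, so
`grid_edges()` reconstructs them as geometric midpoints of adjacent group
energies, extended log-symmetrically at both ends. `rebin()` moves group
fluences between grids by fractional overlap in log energy (i.e. assuming
the fluence is flat per unit lethargy inside a source bin) and conserves
total fluence whenever the target covers the source. On the output grid the
bin around the 1.87 MeV group is wide (its neighbors are 1.03 and 10.3
MeV), which matters for fast-peak bookkeeping below.

## Response functions

Measured sphere response matrices are facility specific and not generally
published; the package therefore ships a parametric stand-in
(`parametric_response()`) and reads real calibrations from CSV
(`read_response_csv()`). The parametric family has the qualitative features
of moderator-sphere responses:

* a log-normal bump in energy whose peak energy grows exponentially with
  diameter, $E_p(d) = 2.5\times10^{-8}\,e^{kd}$ MeV with
  $k = \ln(3.2\times10^8)/12$ per inch, placing the bare-cube sensitivity at
  thermal energy and the 12-inch peak near 8 MeV;
* a bump width of 2 in $\ln E$ and an amplitude growing mildly
  ($1 + 0.05\,d$) with diameter;
* a Maxwell-shaped thermal term for the bare cube;
* a hard cadmium cutoff: covered configurations respond zero below
  5e-7 MeV (0.5 eV), the standard cadmium cutoff for a 0.5 mm cover. By
  default the spheres are covered and the bare cube is not, matching the
  physical campaign.

Absolute response scales cancel in unfolding whenever training and
deployment use the same matrix; readings are kept in fluence-equivalent
units throughout.

## Synthetic spectra and the compendium emulation

Reference spectrum libraries cannot be redistributed here, so
`sample_compendium()` emulates one parametrically. Each spectrum is a
mixture of 2–4 families — thermal Maxwellian, 1/E epithermal tail,
evaporation, Watt fission, and a broad Gaussian in lethargy — with mixture
weights from a flat simplex. Components are discretized as exact bin
integrals of their densities (closed forms where available, adaptive
trapezoid in log energy for the Watt form) and normalized to unit fluence.

Parameter ranges are chosen to be physically representative of workplace
and calibration fields rather than maximally diverse:

* thermal Maxwellian temperature `kT = 2.53e-8 * U(0.8, 1.2)` MeV — thermal
  neutrons equilibrate near the moderator (room) temperature, so only a
  ±20% band is physical, not orders of magnitude;
* 1/E windows starting at a few kT (2e-8 to 1e-7 MeV) and ending where a
  fast peak takes over (0.01–1 MeV);
* evaporation temperatures 0.2–1.5 MeV and Watt parameters
  a ∈ [0.9, 1.2] MeV, b ∈ [2.5, 3.5] MeV⁻¹, covering photoneutron and
  fission sources;
* lethargy-Gaussian widths of 1–2 in ln E: structures much narrower than
  that are below the intrinsic resolution of a moderating-sphere set and do
  not occur in moderated workplace fields.

This matters scientifically: a bias-free linear network reading 9 detector
values can only ever reproduce spectra living near a 9-dimensional linear
manifold. If the synthetic family is made artificially rich (e.g. thermal
temperatures spread over a decade, half-decade-wide spectral needles), even
the *exact* least-squares unfolder fails with ~20% median error — a
statement about the family, not about any trainer. The ranges above keep
the emulation honest to the physics while remaining learnable, and the
round-trip tests should be read accordingly: they validate the pipeline on
smooth, workplace-like spectra, and say nothing about fields with
structures sharper than the spheres resolve.

Measurement noise is modelled where it physically arises, in the track
counts: expected tracks = calibration × reading + background, Poisson
sampled, converted back to fluence with `sd = sqrt(tracks)/calibration`
(`noise_model()`, default background 50 tracks cm⁻²). "1% noise" in the
validation experiments means the calibration is set so the median detector
expects 1e4 tracks.

The `"photoneutron"` preset encodes the canonical two-peak shape of a linac
field — thermal Maxwellian (weight 0.15), 1/E tail (0.25), evaporation peak
with T = 0.4 MeV (0.60) — and the `"cf252"` preset a Watt fission spectrum
with a = 1.025 MeV, b = 2.926 MeV⁻¹, the standard constants for a ²⁵²Cf
source.

## The unfolder

The unfolding network is deliberately minimal, mirroring the instrument's
original software: linear, no biases, no hidden layer. Its weight matrix W
(25 × 9) maps readings to group fluences, trained to minimize the mean
squared error over (spectrum, readings) pairs built by `training_set()`:
compendium spectra on the 60-group grid, folded noiselessly (optionally
with Poisson augmentation) into readings, targets rebinned to the 25-group
output grid.

Training uses full-batch resilient backpropagation (Rprop): one adaptive
step size per weight, grown by η⁺ = 1.2 on a consistent gradient sign,
shrunk by η⁻ = 0.5 on a sign flip (skipping that step), clamped to
[Δmin, Δmax]. Defaults are the standard published constants (Δ₀ = 0.1,
Δmax = 50, Δmin = 1e-6, 2000 epochs, tolerance 1e-10). Two implementation
choices are worth stating:

* **Monotone safeguard.** Plain Rprop does not guarantee a monotone loss.
  After each epoch the candidate update is accepted only if the training
  loss did not increase; otherwise all step sizes shrink and the sign
  memory is cleared. The reported loss history is therefore non-increasing
  by construction.
* **Normalization.** Inputs and outputs are scaled per feature to unit
  maximum during training and the denormalized weights are stored. For the
  un-penalized quadratic loss this rescaling leaves the optimum itself
  unchanged (row-wise least squares is invariant under diagonal output
  scaling), so the converged network can be compared directly with the
  closed-form solution on the raw scale.

Because the nine sphere responses overlap strongly, the normal equations
are ill-conditioned (condition number of AAᵀ around 1e6), and reaching the
least-squares optimum takes far more epochs than the 2000-epoch default:
the equivalence experiments train with `tol = 0` (no early stop),
`delta_min = 1e-14` and 1e6 epochs, about a minute of CPU, after which the
trained weights agree with `ls_oracle(ridge = 0)` to well below 0.1%
relative Frobenius distance on the same training data. The default
configuration is fine for exploratory use; full convergence is only needed
when the network is to *be* the least-squares solution.

`ls_oracle()` computes that closed form,
$W = \Phi A^\top (A A^\top + \lambda I)^{-1}$, and is kept strictly
independent of the trainer so it can serve as its oracle. `unfold()`
applies the weights and clips negative group fluences to zero (recording
which groups were clipped); the linear network cannot enforce
nonnegativity itself. `unfold_uncertainty()` propagates reading
uncertainties by Monte Carlo (Gaussian perturbations truncated at zero).

## Validation experiments and their truths

The test suite and `scripts/acceptance.R` rerun these experiments at fixed
problem sizes: 500 training pairs, 50 held-out spectra, the two presets.

* **Round trip.** Noiseless fold → unfold of held-out compendium spectra,
  scored by relative L2 error against the spectrum rebinned to the output
  grid. The median error sits near 10%; it depends on the random held-out
  draw and can land on either side of that value for different seeds. This
  is the irreducible price of compressing a spectrum into nine readings,
  not a training artifact.
* **Preset recovery.** For the photoneutron preset the truth is its *exact*
  discretization on the output grid (`spectrum_preset("photoneutron",
  build_output_grid())`), i.e. exact bin integrals of the continuous
  density — not the lethargy-flat rebin of the 60-group representation,
  which is an approximation. The distinction matters because the preset's
  fast region puts nearly equal fluence (0.7% apart) into the 0.578 and
  1.03 MeV groups; against the exact truth the unfolder recovers both peak
  groups exactly and their heights to a few percent under 1% counting
  noise.
* **Fission check.** Unfolding a noiseless ²⁵²Cf (Watt) exposure must put
  the spectral peak inside the fission hump (0.5–2.5 MeV) and reproduce the
  mean energy of the continuous Watt form (2.306 MeV by closed form
  3a/2 + a²b/4) to within 15%. The recovered mean lands systematically
  ~13% high: the output grid's last bin spans roughly 4.4–24 MeV with
  representative energy 10.3 MeV, so whatever Watt tail falls there is
  booked at 10.3 MeV. This is a property of the published 25-group
  reporting grid, not of the unfolder.

## Degenerate inputs and numerical conventions

* Peak searches split the grid at 1e-6 MeV (thermal bound) and 5e-2 MeV
  (fast window start), both configurable; ties break toward the lower
  energy group, which is required because the published mean column
  contains an exact thermal tie (6.66e5 at both 3.28e-8 and 5.78e-8 MeV).
* The published reference table's mean column is *not* the arithmetic mean
  of its six side columns in every row, and sides A and B are identical in
  all but the first row — reproduction artifacts of the original table.
  `check_reported_mean()` flags rows deviating by more than 1% instead of
  trusting them; assertions are made only on verified rows.
* The fluence-weighted mean energy of that published mean column is
  ≈ 0.198 MeV, well below the 0.48 MeV quoted for the same field in the
  original analysis, whose averaging definition is not stated. The package
  deliberately reports the plain fluence-weighted mean and does not force
  agreement.
* A monitor unit is taken as 1 MU = 1 cGy at the depth of maximum dose, so
  the 5 Gy reference exposure corresponds to 500 MU.
* Spectra with zero total fluence have no mean energy (error); a zero dose
  equivalent makes the fast dose fraction undefined (error). Track-density
  conversions floor at zero fluence.
* Dose-equivalent coefficients are user supplied (`read_coefficients_csv()`),
  grid aligned; only a flat demonstration table ships with the package, so
  shipped examples report fluence fractions, not ICRP-weighted doses.

## Known limitations

* The parametric response family is a stand-in; quantitative agreement with
  any particular facility requires loading its measured/simulated matrix.
* The linear unfolder has a 9-dimensional range: spectra with more
  structure than the spheres resolve are smoothed, and the round-trip error
  quantifies exactly that.
* Location-to-location scatter effects in a real bunker (maze softening,
  room return) are outside the synthetic model; the generator emulates
  spectral shapes, not transport.
* Negative-fluence clipping is post-hoc; heavily noisy readings can push a
  group to zero and bias its Monte-Carlo uncertainty near the boundary.
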