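---
title: "Models and methods behind mbrt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mbrt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrt)
```

`mbrt` models the complete simulation chain of orthovoltage X-ray minibeam
radiotherapy (MBRT) of intraocular targets: a polyenergetic virtual source,
a divergent multi-slit brass collimator, a 3 cm air gap, and a voxelized
eye/head phantom in which dose-to-medium is scored and analysed. This
vignette explains the models, their assumptions, the tunable parameters,
and the deliberate design choices, so that results can be interpreted —
and their limits understood — without reading the source code.

## Source spectrum

The source is a discretized energy spectrum: photon energies on a uniform
1 keV grid with all contributions below 21 keV removed and the remainder
renormalized (low-energy photons cannot traverse the collimator or reach
the target and only cost simulation time). `default_spectrum_220kv()`
ships a *generic* 220 kVp tungsten-anode-like spectrum built from Kramers
bremsstrahlung filtered by 0.15 mm of copper; it is a stand-in with the
right qualitative shape (mean energy ≈ 82 keV) rather than a measured tube
spectrum, and characteristic lines are not modelled. Measured spectra can
be supplied as two-column text files via `read_spectrum()`. A
monoenergetic mode (`energy_spectrum(E, 1)`) supports analytic
validation.

## Collimator geometry and transmission

Each collimator is a 30 mm brass block with 3 or 5 divergent slits. Slit
*k* is a prism tilted by its axis angle; its centre at depth *t* into the
block is `exit_offset_k − (T − t)·tan(angle_k)` and its width is linearly
interpolated between the tabulated stations (entrance/mid/exit widths for
5-slit geometries, entrance/exit for 3-slit; the mid width applies at the
mid-plane, the natural reading of the three tabulated widths). The slit
height bounds the aperture vertically with straight edges, since the
slits generate *planar* minibeams. Five presets (A, Ah, A3s, B, C) cover
slit widths of 400–500 µm, divergence angles of 0.595–0.744° and exit
spacings of 1150–2425 µm; user geometries use the same YAML schema
(`inst/extdata/collimators.yaml`).

`transmit()` computes the brass path length of a ray by exact analytic
intersection with the union of slit prisms (piecewise-linear inequalities
in the depth coordinate), and the engine applies the weight factor
`exp(−µ_brass·path)`. An **ideal-absorber mode** kills any ray that
touches brass; with 3 cm of brass the spectrum-averaged physical
transmission is far below 10⁻⁴ (about 2 % only at the 220 keV endpoint),
so the toggle changes results negligibly while making the geometry checks
exact and fast.

### Source models and the slit-axis convergence point

Back-projecting the tabulated exit offsets and divergence angles shows
that the slit axes of these geometries do **not** converge at a single
focal point (the central-adjacent pair converges ≈ 8 cm behind the
collimator, the outer pairs tens of centimetres). No point-source
placement can therefore send every beamlet along its slit axis. The
package consequently offers three source models:

* `"aligned"` (default for pattern work): each slit is illuminated by a
  fan of rays parallel to its own axis — the design condition of a
  divergence-matched collimator. Beamlet centres then follow the
  geometric projection `projected_pattern()` exactly, and the
  centre-to-centre spacing grows with depth as `z·tan(angle)`
  (0.208 mm over 2 cm for collimator A).
* `"point"`: a point source at a configurable distance (default 350 mm)
  behind the entrance, sampling the entrance aperture uniformly. This
  adds realistic partial-transmission penumbra but, because of the
  non-convergence above, clips the outer slits of 5-slit geometries.
* `"parallel"` / `"pencil"`: axial beams for analytic physics tests.

Measured beamlet positions are reported both as the profile argmax and as
the dose-weighted **centroid** within the detection window; the centroid
is the meaningful position estimate for the flat-topped beamlets the
ideal source produces and is used in the pattern tables.

## Phantom generator

`make_head_phantom()` builds the study geometry in a beam-aligned frame
(beam along +z, slits spaced along x): a 2 mm air layer; a 24 mm-diameter
spherical eye with its anterior pole at the surface; a 3 mm
cornea/anterior-chamber water layer; a 9 × 4 mm ellipsoidal lens starting
at 3 mm depth; water-equivalent vitreous; a 1 mm retina shell lining the
posterior hemisphere; a 4 mm-radius spherical target centred at 20 mm
depth on the beam axis (the depth of a typical posterior intraocular
tumour); a 6 mm bone slab from 26 mm; and soft tissue (brain) behind it.
All extents are configurable, and every ROI is defined constructively
from the configuration, which is stored with the phantom for
reproducibility. Materials (air, water, soft tissue, lens, cortical-bone
like bone) use standard tissue-substitute compositions; the bone/tissue
contrast at kV energies is the feature that matters.

The four irradiation positions are emulated as follows: **P1** is the
central head-on worst case through lens and optic axis. **P2** (peripheral
entry) offsets the eye 6 mm in the slice-normal direction so the beam
enters through peri-ocular skin and the lens lies outside the analysed
central slice; the entry ROI is labelled `skin` instead of
`anterior_chamber`. **P3** is a partially offset variant that keeps the
lens in the slice. **P4** stands in for an oblique setup: the beam path
crosses a thicker (9 mm) bone slab and the distal ROI is labelled
`tissue` rather than `brain`. These are desk-scale surrogates for the
angled CT-based setups of a full study; the ROI row sets match the
corresponding reported cases.

`ingest_ct()` accepts NIfTI volumes (or plain arrays with spacing) and
maps Hounsfield units to materials piecewise-constantly (< −400 air,
−400…150 soft tissue, > 150 bone by default); ROI labels are never
inferred from images and must be supplied as a label volume.

## Photon transport

The Monte Carlo engine (C++ via Rcpp) transports photons only:

* **Free paths** are sampled by Woodcock (delta) tracking against a
  majorant cross-section — the maximum linear attenuation over all
  phantom materials at the current energy — which is exact in
  heterogeneous voxel grids without ray-voxel traversal.
* **Compton scattering** samples the Klein–Nishina differential cross
  section with Kahn's rejection method; the energy transferred to the
  electron is deposited at the interaction site (kerma approximation),
  and the photon continues with the scattered energy and direction.
* **Photoelectric absorption** deposits the full photon energy locally
  (no fluorescence).
* **Rayleigh scattering** changes direction without deposit, sampled from
  the Thomson angular law; the atomic form factor (which would make it
  more forward-peaked) is not modelled.
* Photons below the cutoff (default 5 keV, where the tissue mean free
  path is far below a voxel) are absorbed locally.

The kerma approximation is the dominant fidelity gap relative to a
condensed-history code: secondary electrons of ≤ 220 keV have
sub-millimetre CSDA ranges in tissue, comparable to the 0.1–0.5 mm
scoring voxels, so beam edges are modelled slightly sharper than reality.

Attenuation data are parametric per-element cross sections tabulated per
material on a logarithmic 10–300 keV grid: exact Klein–Nishina incoherent
scattering for free electrons, and power-law photoelectric
(∝ Z⁴·⁵/A·E⁻³) and coherent (∝ Z²·⁵/A·E⁻¹·⁹) terms anchored to water
values at 30 keV. They reproduce water within a few percent over the
orthovoltage range and preserve the bone/soft-tissue contrast, but they
are approximations, not evaluated nuclear data; every quantitative
transport test in the package is therefore formulated against the
*shipped* tables (e.g. primary attenuation versus `exp(−µx)` with the
same µ), never against external reference values. Lookups below 10 keV
clamp to the 10 keV value; such photons are within one cutoff length of
absorption anyway.

Energy bookkeeping is exact: for every run, emitted = deposited +
escaped + absorbed-in-collimator to within double-precision rounding
(≈ 10⁻¹⁵ relative; the suite enforces 10⁻⁹). Post-collimator statistical
weights below 10⁻⁷ are terminated and booked as collimator absorption,
which preserves closure while avoiding near-zero-weight histories.

### Batches, seeds and uncertainty

A simulation combines `n_instances` independent instances of
`n_histories` each (the study-scale convention is 300 instances; desk
runs use 5–10). Instance seeds derive from the master seed through a
Lehmer multiplicative generator whose arithmetic is exact in double
precision, and each seed is expanded into an independent xoshiro256**
stream inside the engine, so runs are bit-reproducible across platforms
and instances are statistically independent (verified by chi-square tests
of pooled interaction-depth histograms). The per-voxel uncertainty is the
standard deviation of the instance doses; the **global uncertainty** is
the mean of std/dose over an analysis mask restricted to the analysed
region, because near-empty, very-low-dose voxels would otherwise dominate
and distort the score. At desk-scale history counts this global figure is
tens of percent; reaching the few-percent level of a full study requires
the 300-instance, multi-hour configuration, which changes no code path —
only `transport_config()`.

## Dose analysis

A 0.1 mm-thick central slice (or one voxel, if coarser) is extracted
perpendicular to the slit-height direction; lateral profiles are taken at
selected depths. Detection is anchored to geometry rather than to the
noisy profile: each **peak** is the maximum within ±ctc/4 of its expected
centre from `projected_pattern()` (ties break toward the window centre),
and each **valley** is the minimum over the open interval between
adjacent detected peaks. A profile whose windows contain no modulation
above the adjoining valleys is treated as degenerate; ROI summaries then
fall back to the profile extrema, so a uniform region reports PVDR 1
rather than an error. **FWHM** is measured from zero dose (the
conventional definition in the minibeam literature, not
valley-subtracted) by linear interpolation of the half-maximum crossings
nearest the peak, and is flagged unmeasurable when beams overlap so much
that no crossing exists within the window.

ROI summaries report the mean dose over the ROI in the analysed slice and
peak/valley/PVDR at the ROI's profile depth — by default mid-ROI, and for
the longitudinally extended brain/tissue ROIs two depths at 1/4 and 3/4
of the ROI extent, reported as a range ordered shallow to deep. `Dpeak`
is the maximum over all detected peaks and `Dvalley` the minimum valley
(a per-peak breakdown stays available on the profile object). Relative
tables fix the target mean at 100 %; `scale_to_prescription()` multiplies
every dose by prescription/100 (default 30 Gy, a mean target dose typical
of preclinical X-ray MBRT), leaving PVDR unchanged by construction.
Report tables round half-away-from-zero to one decimal while full
precision is kept internally — PVDR is always recomputed from unrounded
peak and valley values.

## What the validation shows — and what it does not

The test suite and `scripts/acceptance.R` validate: the worked-example
arithmetic on published dose tables (PVDR recomputation and
prescription scaling); the engine against closed forms (exponential
primary attenuation, inverse-square fluence, Klein–Nishina moments by
numeric integration); the collimator model against a dense point-sampling
oracle and mirror symmetry; beamlet positions and spacing growth against
trigonometric projection; the 1/√N scaling and region-restriction
behaviour of the uncertainty estimator; exact energy closure; and the
recovery of generator parameters from synthetic Gaussian combs. Typical
problem sizes are 10⁵–10⁶ histories per check and 10⁶–3×10⁷ for the
ordering study — sizes chosen so the whole suite runs in well under half
an hour on one core.

Passing these checks does **not** mean the absolute dose tables of a
patient-CT study are reproduced. With the idealized aligned source and
no electron transport, beamlets stay nearly slit-width (FWHM ≈ 0.4 mm at
the surface versus ≈ 0.7 mm measured with a real focal spot), valleys are
much shallower-filled, and PVDRs at 2 cm depth in water come out an order
of magnitude above the published clinical-geometry values — the *ordering*
across collimators (A < B < C with increasing slit spacing) is the
physically meaningful, and verified, statement. Likewise the
per-case global uncertainty percentages of a 300-instance study are not
reproducible at desk scale and are not targeted.

## Known limitations

* Photon-only transport (no secondary electrons, bremsstrahlung,
  fluorescence or polarization); kerma-approximated deposition.
* Parametric attenuation tables; Rayleigh without form factors.
* Generic 220 kVp spectrum stand-in; no focal-spot size model.
* Layered/spherical synthetic anatomy only; angled irradiations are
  emulated by construction (offsets, thicker bone), not by rotating a CT.
* Single minibeam arrays; interleaved multi-array irradiations are out of
  scope.
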