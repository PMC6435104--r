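---
title: "Modelling and optimizing BOLD sensitivity in 2D EPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing BOLD sensitivity in 2D EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldsens)
```

## The model and its assumptions

BOLD sensitivity (BS) is modelled as the product of the local echo time and
the signal intensity, `BS = TE * I`: the sensitivity of a gradient-echo
signal to a small change in the effective relaxation rate is largest when
the echo is late and the signal still strong. `boldsens` evaluates, per
voxel, how a local susceptibility-induced field gradient — expressed in the
slice frame as readout, phase-encode and slice components
(`G_RO`, `G_PE`, `G_SL`) — alters this product relative to a well-shimmed
voxel:

* **Through-plane dephasing.** Spins across the slice profile dephase at a
  rate set by `G_SL`. For a Gaussian excitation profile of thickness `dz`
  the attenuation is `exp(-Psi^2)` with
  `Psi = gamma * dz / C * (G_SL * TE + M_shim)`. A z-shim gradient moment
  `M_shim = -G_SL * TE` rephases the slice exactly.
* **Echo shift along PE.** `G_PE` adds to the phase-encode blips, so the
  k-space centre is reached earlier or later: `TE = TE0 / Q` with
  `Q = 1 -/+ (gamma/2pi) * dt_eff * FoV_P * G_PE`, the sign selected by the
  PE gradient polarity. The initial intensity scales with `1/Q`, giving the
  combined factor `Q^-2` in BS. A *prolonged* local TE can raise BS above
  its well-shimmed value — the model deliberately allows that, and the
  optimizer exploits it.
* **Dropout.** The echo must stay inside the acquisition window: along PE
  the local TE must lie in `[TE0 - TA/2, TE0 + TA/2]` for a symmetric
  readout of duration `TA`; along RO the accumulated k-space shift
  `|gamma * TE * G_RO|` must not exceed `pi / dx`. Outside either bound BS
  is exactly zero. A non-positive `Q` (total echo loss) is routed through
  the same dropout path rather than raising an error.

Assumptions worth keeping in mind: thermal noise is treated as constant
(physiological noise, motion and vessel effects are out of scope), k-space
sampling is symmetric (partial-Fourier protocols are rejected at
construction), one parameter set serves all slices, and slice coverage
changes from tilting are not modelled — gradients are projected voxel-wise
into the tilted frame instead of resampling the volume, which avoids
interpolation error at the cost of ignoring coverage effects.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `te0` | ms | 30 (preset I) | BOLD-optimal TE at 3 T for cortex |
| `echo_spacing` | ms | 0.5 | typical unaccelerated EPI readout |
| `slice_thickness` | mm | 3 | sets the dephasing rate in `Psi` |
| `t2star` | ms | 50 | typical grey matter at 3 T; not stated by the source study, configurable per protocol |
| `grappa_factor` | – | 1 | modelled as `dt_eff = dt / R`, shortening `TA` — the standard parallel-imaging distortion scaling |
| `pe_oversampling` | fraction | 0 | enters both the acquired line count and the acquired `FoV_P` |
| z-shim grid | mT/m·ms | −5…5 step 0.5 | search space of the shim moment |
| tilt grid | degrees | −45…45 step 5 | slice angulation / in-plane rotation range |
| `max_loss` | fraction | 0.15 | hard boundary condition on the BS loss in well-shimmed tissue |
| `gamma` | rad/s/T | 2.6753e8 | fixed package-wide (γ/2π ≈ 42.58 MHz/T) |
| `profile_constant` | – | `4*log(2)` | see below |

**The profile constant.** The dephasing term is printed in the literature
with denominator `4 ln 2`; the analytic constant for a Gaussian profile
specified by its full width at half maximum would be `4 sqrt(ln 2)`.
Published summary numbers are not exactly consistent with either choice, so
the package defaults to the printed `4 ln 2` and exposes
`bs_config(profile_constant =)`. With the default, a 1 mT/m·ms net moment at
3 mm slices costs 8% well-shimmed BS, which makes z-shims beyond
±1.4 mT/m·ms infeasible under the 15% rule.

**TE in the dropout and dephasing terms.** After the echo shift, "TE" means
the local TE. The package uses the local TE both in `G_SL * TE` (so z-shim
compensation targets the actual echo) and in the RO dropout bound;
`bs_config(dropout_te_mode = "nominal")` restores the strict as-printed RO
bound at `TE0`.

**Tie-breaking.** The search grid is totally ordered: smaller `|zshim|`
first, then smaller `|tilt|`, then positive polarity, and positive values
before negative at equal magnitude. Exact BS ties — common for symmetric
fields — therefore resolve deterministically toward the cheapest setting.
The ±45° tilt equivalence that symmetric regions exhibit is resolved the
same way; it is a convention, not physics.

## Slice-frame conventions

Scanner axes are X (right–left), Y (posterior–anterior), Z (head–feet). The
PE axis points anterior→posterior for transverse and sagittal slices and
feet→head for coronal slices. Tilting rotates (PE, SL) about RO for
transverse and coronal slices and (RO, PE) about SL for sagittal slices
(in-plane rotation); a positive transverse tilt tips the anterior slice edge
toward the feet. The rotation senses for sagittal and coronal slices are
fixed so that transverse and sagittal frames share the same PE axis at equal
tilt; where the original definitions are only pictorial, the encoded choice
is a documented package convention, unit-tested against the three canonical
frames.

## What the synthetic phantom emulates — and what it does not

`default_head_phantom()` superposes the analytic external dipole fields of
four spherical air cavities (Δχ = 9.4 ppm, B0 = 3 T): two inferior-anterior
(paranasal sinuses) and two inferior-lateral (ear canals), under an
ellipsoidal brain mask with five labelled ROIs above the cavities. The
cavity geometry was fixed once so that the peak gradient magnitude inside
the mask (173 µT/m, 99.9th percentile 112 µT/m) sits on the ±100 µT/m scale
observed over orbitofrontal and temporal cortex in vivo. The sphere-dipole
superposition was chosen over an FFT susceptibility convolution because it
is analytically differentiable, which ties the phantom to the numerical
gradient operator through an exact oracle.

The phantom reproduces the *structure* that drives protocol optimization —
left–right symmetric Y/Z gradients, antisymmetric X gradients, opposing
gradient signs close together — but not anatomy: no tissue heterogeneity,
no shim-system residuals, no physiological noise. A green test on the
phantom therefore establishes that the machinery (projection, search,
constraint, tie-breaks) is correct, not that a specific in-vivo gain will be
realised. Cohorts (`make_cohort()`) jitter cavity centres and radii by a
seeded 5% — enough to spread per-subject optima over a few grid steps, which
is the regime the per-subject histograms are meant to summarise.

## Closed-loop validation design

`simulate_epi_complex()` forward-simulates the acquisition per PE column:
line `m` is sampled at `t_m = TE0 + m*dt_eff` and encodes `k_m = ±m*dk`,
with off-resonance phase `exp(i*2π*f*t_m)`, T2* decay, and through-plane
attenuation evaluated at each sample time. Reconstruction is the nominal
inverse DFT, so echo shifts, intensity scaling and geometric distortion
*emerge* rather than being imposed; the simulator shares no code with the
closed-form model it validates.

The validation field map (`validation_field_map()`, labelled synthetic) is
linear along PE within each column, with triangle-wave slope profiles across
readout columns. Two deliberate choices:

* a column-constant PE gradient makes the EPI distortion a uniform
  per-column stretch, so simulated and estimated gain maps can be compared
  voxel-wise without the undistortion step that real data require (and which
  is out of scope here);
* triangle waves minimise the incidental readout-direction gradient
  (`d²f/dx·dy * y`), which the 1D simulator cannot encode and which would
  otherwise trigger the model's RO dropout where the simulation shows none.

The simulated object fills the PE field of view: the DFT encoding is
periodic, so a full-FoV object has no edges to ring or displace; the
comparison mask keeps clear of the PE boundary where wrapped content carries
the opposite edge's off-resonance. Under this design the phase-difference
estimator recovers the model's local TE to < 0.3 ms (echo spacing 0.5 ms)
and mean BS-gain differences stay below 0.1 percentage points; the residual
per-voxel scatter for polarity-flipped comparisons (sd ≈ 7%) comes from
comparing two differently-distorted reconstructions voxel-wise, which is the
same reason measured validations report per-voxel standard deviations of
10–20%.

## Numerical choices and degenerate inputs

* Derivatives: spacing-aware central differences, one-sided at volume edges
  (kept, not dropped — `erode_mask = TRUE` flags them for downstream
  statistics). Exact for affine fields everywhere; for the dipole field at
  2 mm voxels the truncation error is below 2% at probe distances ≳ 28 mm
  and grows toward the source — that is a property of the stencil, not a
  bug, and the tests probe accordingly.
* Phase unwrapping: 3D region growing (6-connected breadth-first) from the
  most reliable voxel (maximum magnitude, else the mask centroid). It
  anchors the global 2π offset at the seed, so the seed must lie in the
  ±1/(2ΔTE) capture range; pre-computed field maps in Hz are the preferred
  input path.
* The well-shimmed loss depends only on `|zshim|`, so infeasible parameter
  sets are filtered before the argmax — equivalent to "take the next best
  feasible set" but done once, not per voxel.
* `bs_gain` is undefined (NA) when both inputs are zero (e.g. mutual
  dropout); ROI means skip NA voxels.
* Empty ROIs produce an NA row, not an error; a grid missing the reference
  point is refused, because gains would be undefined.
* Memory: `evaluate_grid()` materialises the full set × voxel stack only
  below `max_dense_elements` (default 2²⁴); the optimizers always stream one
  parameter set at a time through the same `bs_relative()` path, so streamed
  and direct evaluations agree bitwise.

## Open design points, resolved

* **Oversampling of the validation protocol:** the printed 13% is
  inconsistent with the stated 74 acquired lines for a 64 matrix
  (74/64 − 1 = 15.625%); the line count is authoritative, so the `"invivo"`
  preset uses `pe_oversampling = 10/64`, forcing TA = 37 ms. Oversampling is
  applied only when declared; presets I–III carry none.
* **Closed-form z-shim recovery** is asserted on a z-shim-only search: with
  tilt free, converting part of a pure slice gradient into a PE gradient
  buys an echo-shift BS boost that beats perfect compensation — the
  full-grid optimum is *better*, and is asserted to dominate.
* **Pseudo-ROIs** (Whole-Brain, Well-Shimmed) in the cross-ROI impact matrix
  report raw mean gains; the 15% constraint applies to feasibility only.
* **Slice gap:** the dephasing term uses the nominal slice thickness; gaps
  do not enter.

## Known limitations

Multiband/SMS, partial Fourier, slice-wise parameter variation, TE as a
search axis, gradient hardware feasibility (slew/amplitude), registration
and undistortion are all out of scope. The simulator handles untilted
acquisitions only (tilted validation would require resampling the object).
BS comparisons across different spatial resolutions are not meaningful under
the constant-thermal-noise assumption; comparisons across parameter sets at
fixed TE and resolution are.
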