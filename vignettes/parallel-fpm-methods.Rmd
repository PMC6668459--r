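---
title: "Methods: parallel Fourier ptychography for 96-well plates"
author: "fpmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel Fourier ptychography for 96-well plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fpmtools)
```

## The imaging problem

A 96-well plate imager built from 96 miniature microscopes faces three
coupled problems: the plate itself warps by tens of micrometers, so wells
drift out of the ±5 µm native depth of focus; plastic-molded objectives carry
lens-to-lens aberrations of order one radian; and the liquid in each well
forms a curved meniscus that bends the illumination. Fourier ptychographic
microscopy (FPM) addresses all three computationally. A shared LED array
illuminates the plate from a sequence of angles; each angle shifts the
sample's spatial-frequency spectrum relative to the objective's
numerical-aperture (NA) passband, so a sequence of low-resolution intensity
images samples overlapping patches of a wider synthetic aperture. Phase
retrieval fuses them into a complex (amplitude + phase) image at a resolution
beyond the objective's native limit, while *embedded pupil function recovery*
(EPRY) jointly estimates each objective's complex pupil — its aberrations,
including defocus — from the same data.

`fpmtools` implements this pipeline end to end on a desk: illumination
geometry and scheduling, meniscus ray tracing, the coherent forward model and
sensor-noise simulator, EPRY with adaptive step size, blind two-stage
refocusing, Zernike wavefront analysis, frame-stack denoising, and
feather-blend mosaicking. Every test fixture is generated by the simulator;
no instrument data is required or shipped.

## Geometry and illumination scheduling

The default geometry is the instrument design: 8 × 12 wells at 9 mm pitch,
LEDs on a 3 mm lattice (exactly one quarter of the well pitch) at
h = 33 mm above the sample, and an 18 mm × 18 mm LED segment per well
(a 7 × 7 block). Because the segment is twice the well pitch on each axis,
adjacent mini-microscopes share 75% of each segment
(`segment_reuse_fraction(9, 18)`), which is what reduces the array from
96 × 49 = 4704 to 1120 unique LEDs (`build_led_grid()`).

`schedule_parallel_illumination()` lights the whole plate in parallel:
pattern (a, b) of the batch turns on every LED whose lattice indices are
congruent to (a, b) mod m, so simultaneous sources sit m pitches apart. The
choice m = 8 (24 mm separation) keeps at most one lit LED inside each
objective's acceptance cone — radius
`acceptance_radius() = h·tan(asin(NA)) ≈ 7.8 mm` on the LED plane — which the
scheduler re-verifies exhaustively over every (frame, well, LED) triple. A
batch is m² = 64 frames; each well is assigned a source in exactly 49 of
them (its own 7 × 7 segment, a different 49 for each well because the well
pitch is 3 lattice steps while the shift period is 8) and idles in the rest.
This reading reconciles the 64-frame batch with the 49-LED per-well segment
without guessing at hardware intent; the per-well map records which frames
carry data for which well.

Acquisition is restricted to brightfield: frames whose illumination NA
exceeds the objective NA (0.23) are dropped. Of the 7 × 7 segment this keeps
the 21 LEDs within the acceptance cone, giving a synthetic aperture of
NA ≈ 0.23 + 0.20 = 0.43.

## Illumination through the liquid meniscus

A well holding ~100–200 µL of buffer carries about 3 mm of liquid. A flat
liquid layer leaves the tangential spatial frequency of a plane wave
unchanged (Snell's law preserves n·sinθ), but it *does* change which ray
reaches a given field point — the parallax effect — and a curved meniscus
amplifies that strongly. `meniscus_model()` describes the layer stack; the
air–liquid surface is either flat or a spherical cap pinned at the well wall
(one curvature parameter, negative for the concave-up surface of an
untreated well). No standard model of the meniscus surface exists for this
geometry, so the pinned cap is this package's own one-parameter choice; it
reproduces the qualitative concave-lens behavior (a hemispherical cap
triples the center-to-edge incidence drift over a flat surface) but no
attempt is made to reproduce any particular measured drift, whose curvature
is unknown.

`trace_illumination()` solves the LED → surface → field-point ray by damped
Newton iteration on the surface intersection point (finite-difference
Jacobian, tolerance 10⁻⁶ mm, 100-iteration cap, bounded to the well
footprint) and returns the effective grating shift n·(direction
cosines)/λ_vacuum at the sample — exactly what the reconstruction consumes
as `k_eff`. With all indices set to 1 it reduces to the free-space
`illumination_wavevector()`, and for a flat surface to the closed-form
flat-slab refraction; both reductions are tested.

## Forward model and noise

`forward_fpm()` is the standard coherent FPM forward operator: shift the
high-resolution object spectrum by the illumination wavevector (rounded to
the common spectral grid), multiply by the pupil, inverse-transform, record
the squared magnitude at the 0.4 µm sensor sampling. Downsampling is by
spectral cropping so the forward and adjoint operations form an exact pair;
energy conservation per frame (Parseval) is tested to 10⁻⁹. The default tile
is the instrument's 110 µm × 110 µm (275 raw pixels) with upsample 4
(0.1 µm reconstruction pixel); the upsampling factor is this package's
choice, sized so the synthetic passband (2·NA/λ) stays below Nyquist with
margin.

`add_sensor_noise()` models the consumer-grade CMOS chain: Poisson shot
noise at a photon scale (default 2000 photons per intensity unit), Gaussian
read noise (default 5 photons), and a static horizontal band pattern
(default amplitude in the denoising pipeline: 200 photons, i.e. 10% of the
brightfield signal) that repeats identically across exposures — the
structured fixed-pattern noise of the readout electronics. The actual
exposure statistics of such instruments vary widely; these defaults are
stand-ins chosen to mimic a low-dynamic-range sensor qualitatively, and they
are deliberately not tuned per experiment. All randomness flows through one
integer seed; identical seeds give bit-identical datasets.

What the simulator does *not* emulate: partial coherence within one LED,
objective field curvature and field-dependent aberrations, meniscus
evaporation dynamics, sensor temperature drift, and fluorescence
photophysics. Passing tests therefore demonstrate the correctness and
robustness of the algorithms under the stated optical model, not instrument
performance.

## EPRY phase retrieval

`epry_reconstruct()` initializes the object as the bilinearly upsampled
square root of the most axial frame (zero phase) and the pupil as the ideal
circ function, then sweeps frames in ascending |k| order (most axial first —
the standard low-NA-first ordering that stabilizes early iterations). For
each frame the pupil-supported sub-spectrum is propagated to the sensor, its
magnitude replaced by √I, and the mismatch ΔΨ fed back:

* object: `O ← O + α·conj(P)·ΔΨ / max|P|²`
* pupil: `P ← P + β·conj(O)·ΔΨ / ((1−γ)|O|² + γ·max|O|²)`, support-masked,
  amplitude clamped at 1.5.

The pupil denominator is the one place this implementation departs from the
textbook EPRY update (`/ max|O|²`). With a brightfield-only LED set the
illumination NA (≤ 0.20) never carries the transmitted DC peak to the outer
pupil rim, so under max-normalization rim updates scale like |O|/max|O| ~
10⁻² and the pupil stalls far from the truth regardless of epoch count. The
regularized denominator (γ = 0.01, the standard rPIE-style weighting; γ = 1
recovers the plain rule via `recon_config(pupil_reg = )`) lets weakly
illuminated pupil regions keep pace: 0.8 rad of injected astigmatism is
recovered to < 0.1 rad RMS (piston/tilt removed) within ~60 epochs, which
the test suite asserts.

The *adaptive step size* rule is deliberately simple and is this package's
concrete choice: if the epoch residual fails to improve by at least 1% for
2 consecutive epochs, both steps are halved. The residual is

`Σ_j Σ_px (√I_j − |ψ_j|)² / Σ_j Σ_px I_j`,

normalized by total measured energy so values are comparable across tiles
(`reconstruction_residual()`); it is zero exactly when the forward model
reproduces every frame's magnitude, and is invariant to the global phase of
the object. The recovered object is defined up to a global phase and a
sub-pixel shift; tests fix this gauge by cross-correlation registration
against the simulator's ground truth before computing any error.

## Blind two-stage refocusing

Defocus is an aberration — the quadratic (Noll index 4) term — so an axial
shift δz can be removed by multiplying the pupil with the angular-spectrum
kernel `φ(f) = 2π·δz·(√(1/λ² − |f|²) − 1/λ)` (`defocus_phase()`, anchored to
zero on axis). `refocus_search()` estimates an unknown δz blindly:

1. **Stage 1 (linear search):** candidates over ±z_range at a 5 µm coarse
   step; each is scored by the residual of a cheap 3-epoch, object-only
   reconstruction with the pupil fixed to ideal × defocus kernel. Pupil
   recovery is off here on purpose: at large defocus the wavefront error
   exceeds 2π and joint pupil estimation is what tends to fall into local
   minima.
2. **Stage 2:** full EPRY seeded at the argmin with the kernel folded into
   the initial pupil, so embedded recovery only absorbs residual aberration.

On simulated tiles the estimate lands within one coarse step of the truth
across ±100 µm, agrees with a dense 1 µm brute-force scan, and restores the
Siemens-star read-out to its in-focus value for |δz| ≤ 30 µm. If the scan
trace shows a second competitive local minimum (prominence above 5% of the
trace range) the search warns and returns the global argmin.

One subtlety in characterizing what refocusing buys: defocus is itself a
pupil mode, so a reconstruction with embedded pupil recovery enabled can
occasionally re-absorb a large defocus on its own — in our simulations it
converges unaided at some shifts (e.g. 30 µm) while stalling in local minima
at others (15–20 µm), which makes the "no refocusing" curve non-monotone.
The no-correction baseline in the tests therefore fixes the pupil to the
ideal one: against that baseline the read-out degrades monotonically once
|δz| exceeds the depth of focus, while the two-stage search holds the
in-focus plateau through ±30 µm and stays within bounds at ±50 µm,
deterministically.

## Zernike analysis

Zernike indexing is Noll throughout (1 piston, 2–3 tilt, 4 defocus, 5–6
astigmatism, 11 spherical); a defocus-as-"fifth-coefficient" convention
corresponds to 0-based counting of the same order and is noted in the
documentation rather than adopted. `fit_zernike()` unwraps the pupil phase
first (quality-guided region growing, quality = pupil amplitude, ties broken
by descending amplitude) and projects onto the first K = 15 modes by least
squares; a noise-free synthesized phase round-trips to 10⁻⁶.
`rotation_invariant_modes()` collapses cos/sin pairs to √(a² + b²) so lens
populations can be compared regardless of how each barrel was rotated during
assembly. Population statistics (astigmatism σ = 0.88 rad, spherical
σ = 0.25 rad, well-depth σ = 17 µm) enter `simulate_well_plate()` as
generator parameters — they are instrument measurements the simulator takes
as given, not quantities it can reproduce.

## Denoising and the fluorescence-like channel

`average_frames()` is the plain per-pixel mean over repeats (σ/√n on white
noise, asserted at the 10-frame regime). `remove_static_pattern()` estimates
the fixed pattern in two stages: the per-pixel median across
illumination-averaged, mean-removed frames isolates what is static across
illuminations, and a projection onto the row profile exploits the pattern's
horizontal band structure. The second stage matters: in-focus brightfield
images change only mildly with illumination angle, so some object content
always survives the median, while its row average is small. On simulated
data the injected band is recovered with correlation > 0.95 and subtraction
is exactly conservative (corrected + pattern = original). With fewer than 3
distinct illuminations the pattern is unidentifiable and the function
refuses. `select_sharpest_plane()` picks the focal plane of a z-stack by
normalized gradient energy (Tenengrad-style, a documented package choice
among the many serviceable sharpness metrics), ties broken toward the
lower z.

## Tiling and mosaicking

`partition_fov()` reads the 110 µm tile as the lattice *step* and extends
each tile box symmetrically so neighbors share ~5% of a tile width (rounded
up to whole pixels, edge tiles clipped). This convention is deliberate: 110
µm tiles that must both overlap 5% *and* cover the 1.1 mm FOV would need 11
columns, while the instrument's stated grid is 10 × 8 — treating the tile as
the step reproduces exactly that grid and guarantees coverage, which a
rasterized oracle asserts pixel by pixel. Per-tile reconstructions carry
independent global phases, so `align_tile_gauge()` first anchors the gauge
on tile 1 and rotates each subsequent tile by the unit phasor maximizing
overlap agreement; `feather_blend()` then averages complex values with
distance-to-edge weights normalized to sum to one. Blending complex values
rather than wrapped phase avoids 2π seam artifacts. A 2 × 2 tiled
reconstruction of a 51 µm bead field agrees with the whole-field
reconstruction to < 5% relative phase RMS.

## Resolution metrics

`star_resolution()` reads the Siemens star by azimuthal contrast in 1-pixel
annuli, sampling 4× the spoke count per ring. Contrast is the modulation at
the star's own frequency (N cycles per revolution) normalized across annuli
— locking onto the spoke harmonic makes the read-out robust to coherent
ringing and noise, which raw min/max contrast is not. The reported
resolution is half the local full period, πr*/N, at the innermost radius
where contrast stays above threshold. The default threshold 0.30 is
calibrated once against the analytic oracle — a star low-passed at cutoff
NA/λ must read λ/(2NA) — and is stored in every report. Star read-outs in
the literature are ambiguous between half- and full-period conventions; all
acceptance-style bounds here are upper bounds, which is robust to that
choice. A raw
single-LED intensity image of a *phase* star is nearly featureless at focus
(the phase information barely couples into intensity), so its read-out is
several times coarser than the restored phase — the simulation shows ~4 µm
against ~0.6 µm restored. `fwhm_resolution()` implements the line-profile
alternative (baseline from the profile ends, linear-interpolated crossings,
one-pixel floor).

## Problem sizes and numerical choices

The test suite runs the full-scale chain (275-pixel tile, upsample 4, 21
brightfield frames, 30 epochs, 10 noisy repeats) for the headline
resolution checks, and a reduced 64-pixel tile with a 16-spoke star for
property sweeps (refocus accuracy across ±100 µm, dense-scan agreement, the
resolution-versus-defocus curve); these sizes are the package's chosen
balance between fidelity and a suite a laptop runs in minutes. Other fixed
numerical choices: illumination shifts are rounded to the spectral grid
(≤ half a frequency pixel, identical in simulation and reconstruction);
pupil amplitude is clamped at 1.5 to guard divergence; the refocus scan
uses 3-epoch object-only reconstructions; archive images are stored as
32-bit float TIFF normalized to [0, 1] with the affine scale in a sidecar.

## Known limitations

* The meniscus surface model is a one-parameter spherical cap; real menisci
  depend on fill volume, coating and evaporation, and the package makes no
  claim to reproduce any specific measured angular drift.
* The simulator's noise levels are plausible stand-ins, not calibrated to
  any sensor.
* Pupil recovery accuracy is quoted at the pupil interior; the outermost
  rim annulus remains the least constrained region under brightfield-only
  illumination.
* Tile-level parallelism is left to the caller (the pipeline is
  single-process); the instrument's GPU/MPI engineering is out of scope.
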