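---
title: "Reverse scan conversion: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse scan conversion: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usrsc)
```

## The problem

A B-mode ultrasound frame is acquired beam by beam: a convex or sector
transducer fires `W` scanlines fanned uniformly over an opening angle
`theta_c`, records `H` echo samples along each, and stores them as an
`H x W` grid (the *echo memory*).  What a clinician sees is that grid
resampled — *scan converted* — onto the Cartesian display raster, where it
becomes the familiar annular-sector picture with black corners.

When display frames are used to train an image classifier, the sector
outline itself is a strong, spurious feature: it encodes the probe, not the
anatomy.  Training on the polar (pre-scan-conversion) representation
removes it, but commercial scanners export only display frames.  This
package recovers the polar representation from the display frame alone:

1. estimate the field-of-view (FOV) geometry from the frame
   (`estimate_fov_geometry()`), and
2. inverse-warp the display raster back onto an acquisition grid with
   bilinear interpolation (`reverse_scan_convert()`).

Around that core sit the forward converter, a phantom generator with known
ground-truth geometry, a batch training-set builder, and a discrete-event
simulator of how a classification network shares a mobile GPU with the
imaging pipeline.

## Geometry model

A convex/sector FOV is an annular sector parameterized by the apex
`(x_offset, y_offset)` in display pixels (the apex may lie off-frame), the
transducer radius `r_c` (apex to FOV top), the opening angle `theta_c`, and
the imaging depth `d_c`.  Coordinates are 0-based pixel centres, `y` grows
downward, and the beam axis points down.  Grid index `(a, r)` —
`a` the scanline index in `[0, W-1]`, `r` the radial sample in `[0, H-1]` —
maps to

$$x = \rho \sin\varphi + x_{\mathrm{offset}}, \qquad
  y = \rho \cos\varphi + y_{\mathrm{offset}},$$

with $\rho = r_c + r\,\Delta r$, $\varphi = -\theta_c/2 + a\,\Delta\theta$,
$\Delta r = d_c/(H-1)$ and $\Delta\theta = \theta_c/(W-1)$.

Two conventions here are deliberate choices, and every tested invariant is
independent of them:

* **Spacing uses `H - 1` and `W - 1` intervals**, so scanline 0 lies on the
  left boundary, scanline `W - 1` on the right, and the first/last radial
  samples on the inner/outer arcs.  This is the convention under which `N`
  uniformly allocated scanlines span the boundaries inclusively, and it
  makes the four grid corners land exactly on the FOV outline — a property
  the test suite asserts to 1e-9.
* **The beam axis is `+y`** (down the screen).  Formulations that put it
  along `+x` differ by a global 90° rotation only.

The inverse transform is arctangent plus radius; its only singular point is
the apex of a zero-radius sector, which is surfaced as `NaN` with a
warning rather than silently assigned an angle.

## Reverse scan conversion without holes

A literal reading of the resampling problem maps every display pixel
forward into the polar grid and then fills the grid positions that received
no sample ("holes") by interpolation.  We implement the equivalent inverse
formulation instead: iterate over the *output* polar grid, map each `(a, r)`
to its continuous display position, and bilinearly sample there.  Under the
same bilinear model the two formulations agree, but the inverse one assigns
every output pixel by construction, needs no hole bookkeeping, and
vectorizes cleanly.  Out-of-bounds sources return 0 (the display
background); the 2×2 stencil clamps at image borders.  The same sampler
drives the forward converter and the `downsample_image()` reduction to the
network input size (64 × 64 by default, no anti-aliasing prefilter —
plain bilinear reduction, consistent with the rest of the pipeline).

Bilinear weights form a convex combination, which yields two cheap,
strong properties the tests exploit: resampled values never leave the
min/max of their stencil, and pointwise-brighter inputs never produce
darker outputs.

## Geometry estimation

`estimate_fov_geometry()` proceeds in three steps.

**Binarization.** The ultrasound image region (UIR) — a configured crop
rectangle, full frame by default — is thresholded at intensity > 0.  The
zero default assumes a pure black surround, which holds for rendered frames
and clean captures; it is configurable for noisy screenshots.  Automatic
removal of on-screen annotations is out of scope: the crop is
configuration.

**Boundary lines.** The FOV's left and right edges are straight scanlines.
We take the mask's morphological boundary (mask minus its 4-neighbour
erosion), run a standard line Hough transform (1° × 1 px accumulator), and
refine each candidate peak by a total-least-squares fit to its inlier
pixels (±1.5 px band, one reweighting pass).  Candidates must tilt more
than 5° from vertical (vertical edges mean a rectangular, linear-array
FOV), less than 85° (rejecting chords of the top/bottom arcs), and sit on
the matching side of the foreground centroid; the strongest peak per side
wins.  Because the boundary layer consists of *foreground* pixels, whose
centres sit up to a pixel inside the true edge, the fitted line is shifted
half a pixel outward along its normal; without this debias the apex of a
wide-radius probe drifts by 1-2 px along the sector bisector.

**Parameters.** The apex is the intersection of the two refined lines and
`theta_c` the angle between them.  Lines alone cannot give radii, so
`r_c` and `r_c + d_c` are the min/max apex distance over foreground
pixels.  `r_c` below `r_sector_max` (default 5 px) classifies the FOV as a
sector and snaps the radius to 0; a missing or near-parallel line pair
(< 2° apart) falls back to `kind = "linear"` with the foreground bounding
box.  The estimator is fully deterministic.

On rendered phantoms over a 27-case grid (`r_c` ∈ {0, 60, 150} px ×
`theta_c` ∈ {40°, 65°, 90°} × random offsets, 500 × 600 canvas) the suite
requires recovery within 1° and 2 px; observed errors are roughly an order
of magnitude smaller, and 100 speckled random-geometry frames must pass at
≥ 95%.

## The phantom generator

The generator exists so that every stage is testable against known ground
truth without clinical data.  It emulates three things about B-mode data:
fully developed speckle (a Rayleigh-distributed envelope, the canonical
amplitude model for many random scatterers per cell), display-style log
compression, and coarse echogenicity contrasts (anechoic fluid ≈ 4,
hypoechoic parenchyma ≈ 60, background ≈ 120–150, hyperechoic
interfaces ≈ 230 on the 8-bit scale).  The compressed speckle is scaled so
its *expected* value equals the region's target mean; the scale factor
`E[log1p(gamma * E)]` is computed by numeric quadrature, so a 10⁴-pixel
region's sample mean lands within ~1 intensity level of its target.
Speckle-off phantoms emit exact region means and are the fixtures for
resampling-fidelity checks.

What it does **not** emulate — and therefore what passing tests do not
show about real data: coherent PSF correlation (speckle here is white
pixel-to-pixel, real speckle has a lateral/axial correlation length),
attenuation and time-gain compensation, refraction/shadowing, probe-marker
and text overlays intruding into the UIR, and real organ shape variation.
The class recipes (`liver` = plain speckle, `kidney` = hypoechoic ellipse
with bright rim, `gallbladder` = large anechoic ellipse) are caricatures
sufficient to exercise the pipeline, not anatomy.

## The dataset builder

`build_training_set()` runs crop → geometry → reverse scan conversion (at
an intermediate 256 × 256 polar resolution, configurable — display frames
carry no record of the acquisition grid size, so this is a free parameter)
→ 64 × 64 downsample, writing 8-bit PNGs and a CSV manifest.  The `usi`
variant skips the geometric step (crop → downsample) and is the baseline
representation in which the FOV outline survives.  By default geometry is
estimated once per batch — a single-probe device has a fixed FOV shape —
with `per_frame_geometry = TRUE` for mixed-geometry batches (the phantom
datasets vary geometry per frame, so tests use this flag).  Failures are
recorded as `skipped:<reason>` rows and never abort a batch; re-runs are
bit-identical.  "Near-zero" in the corner-shedding check means intensity
< 8 of 255: low enough to be background or anechoic, high enough to catch
interpolation-blurred edges of the black corners.

## The scheduling simulator

On a phone-based scanner the GPU does everything.  Each frame's IQ data
takes `t_transfer` ms to arrive; rendering it (IRP) takes `t_irp` ms, which
is much shorter, leaving an idle window of `t_transfer - t_irp` every
frame.  Running a classification pipeline (CP) of per-layer GPU tasks
after each IRP — the frame-synchronous structure (FSC) — stretches the
frame period to `max(t_transfer, t_irp + sum(layer_times))` and throttles
imaging.  The frame-asynchronous structure (FAC) instead splits the CP
into sub-pipelines (sCPs) sized for the idle window and runs exactly one
per window, so imaging proceeds at the transfer rate and one classification
result spans `M` frames, giving `f_image ≈ M × f_cp`.

`split_pipeline()` packs layers greedily in order; layer tasks are
non-preemptive, so a single layer longer than the budget forms its own
flagged, overrunning sCP.  Greedy first-fit is minimal for contiguous
packing, which the tests verify against exhaustive enumeration on short
lists.  The simulators are exact discrete-event traces (no formula
shortcuts), reporting measured mean rates; in overrun-free runs the
`f_image = M × f_cp` relation holds to machine precision, and two
order relations hold for *every* model: FAC never images slower than FSC,
and FSC never classifies slower than FAC.  The idle budget is defined as
`t_transfer - t_irp`; one sCP per window (no multi-sCP packing) matches the
intended interleaving, and `t_irp >= t_transfer` (no idle window) is a
signalled error.  An optional truncated-normal per-task jitter with its own
seed models scheduler-call latency variance; with jitter off the
simulation is exactly deterministic.

A worked example: transfer 25 ms, IRP 4 ms, three 20 ms layers.  FSC gives
a 64 ms frame period (15.6 fps, one classification per frame); FAC splits
into `M = 3` sCPs, restores 40 fps, and completes a classification every
75 ms (13.3 cps) — imaging rate up 156%, classification rate down 15%.

```{r scheduler-example}
model <- timing_model(t_transfer = 25, t_irp = 4,
                      layer_times = c(20, 20, 20))
simulate_fsc(model, 300)
simulate_fac(model, 300)
```

## Numerical choices and degenerate inputs

* Tolerances: coordinate transforms are closed-form and tested to 1e-9;
  geometry recovery to 1°/2 px; forward-then-reverse resampling to
  MAE < 3 intensity levels and normalized cross-correlation > 0.98 on
  smooth phantoms, measured ≥ 10 grid cells from the edges (boundary
  stencils straddle the background and are excluded by design, not
  failure).
* Out-of-bounds samples are 0; no extrapolation.  Border stencils clamp.
* Ties in the Hough accumulator resolve by `which.max()` order
  (deterministic); peak neighbourhoods (±4.5°, ±6 px) are suppressed
  before the next peak is taken.
* Degenerate inputs are signalled with classed conditions
  (`usrsc_linear_fov_error`, `usrsc_no_foreground_error`,
  `usrsc_no_sector_boundary_error`, `usrsc_no_idle_window_error`,
  `usrsc_empty_render_error`) so callers can branch without string
  matching.
* All randomness (phantoms, datasets, jitter) flows through explicit
  integer seeds; seeded code restores the caller's RNG state.

## Problem sizes

The shipped suites use 500 × 600 extraction canvases, 160 × 128 phantom
grids, a 200 × 160 grid on a 600 × 800 canvas for round-trip fidelity,
1e5 transform pairs, 1200 scheduler models, and 3 × 60-frame datasets in
the test suite (3 × 200 in the acceptance script) — sizes chosen so the
whole suite runs in a few minutes on one CPU while leaving every estimate
comfortably inside its tolerance.

## Known limitations

* Only single, centred-ish convex/sector FOVs (and rectangular linear
  frames as a fallback) are modelled; steered-linear trapezoids, dual-FOV
  layouts and Doppler overlays are out of scope.
* The UIR crop is configuration, not detection; frames with annotations
  overlapping the FOV will bias the boundary fit.
* Geometry is expressed in display pixels throughout; no physical (mm)
  calibration.
* The classifier harness is a pixel-space random forest for comparing
  representations on phantoms; it says nothing about CNN accuracy on
  clinical images.
* The scheduler is a timing abstraction: it does not model memory traffic,
  shader occupancy, or transfer/compute overlap.
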