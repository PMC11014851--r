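---
title: "Mapping intracellular growth from quantitative phase movies: models and methods"
author: "qpigrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intracellular growth from quantitative phase movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Quantitative phase imaging measures, per pixel, the optical path
difference (OPD) of light through the specimen. Because the refractive
index excess of cellular dry matter is proportional to its concentration,
OPD integrates dry mass along the optical axis: the areal density is
`sigma = OPD / alpha` (pg/µm²), with `alpha` the specific refractive
increment, 0.18 µm³/pg by default — the standard value for mixed cellular
material, and deliberately a calibration *input* rather than a constant,
since protein- or lipid-dominated samples differ.

At a fixed (Eulerian) location, the observed density obeys a 2-D mass
balance

$$\frac{\partial \sigma}{\partial t} + \nabla\cdot(\sigma\,\mathbf v) = r,$$

so the local change mixes transport with the quantity of interest, the
net source term $r$ (biosynthesis minus degradation). Differentiating
noisy images to evaluate $\nabla\cdot(\sigma\mathbf v)$ directly is
ill-conditioned. Instead the package absorbs the transport term by
construction: it estimates $\mathbf v$ by correlation velocimetry, seeds
small material control volumes on the cell, advects their corners with
the flow, and integrates the mass inside each deformed polygon at every
frame. In this Lagrangian frame the mass of a tracked volume changes only
through $r$, so the ordinary least-squares slope of mass against time
(pg/h) estimates the volume's net growth rate, and its standard error
comes from the usual OLS formula. This is also why no explicit divergence
term appears anywhere in the code.

Assumptions inherited from the imaging geometry: motion along the optical
axis is slow compared to in-plane motion (the balance is 2-D), the
specimen is weakly scattering, and the frame interval samples the motion
finely enough that displacements stay within the correlation search
range. Mitotic rounding violates the 2-D assumption badly; windows in
which whole-cell mass or area jumps by more than 20% between consecutive
frames are therefore excluded with a warning rather than fitted.

## Stage by stage

**Background correction.** A plane `a·x + b·y + c` is fit by least
squares to the off-cell OPD and subtracted everywhere. A plane is the
simplest model consistent with slowly varying illumination and residual
wavefront tilt; the operation is idempotent to numerical precision, which
the tests exploit.

**Segmentation.** Gaussian smoothing (sigma 1 px), a fixed density
threshold (0.05 pg/µm²), largest connected component, hole filling. This
is bookkeeping segmentation — deterministic and adequate for seeding and
whole-cell totals — not morphology. Both knobs are configuration keys.

**Velocimetry.** Interrogation windows are matched between frames by
zero-mean normalized cross-correlation computed via FFT. Three details
matter much more than textbook presentations suggest, and each is the
product of a failure we could measure with the synthetic generator:

1. *Template-in-region matching.* Correlating two same-size windows lets
   content enter and leave the support, which biases broad correlation
   peaks towards zero lag. The implementation instead matches each
   window (template) inside a larger search region of the second frame,
   with per-lag local normalization, so the support is closed and rigid
   displacements are estimated essentially without bias.
2. *Spectral upsampling.* Subpixel refinement evaluates the band-limited
   correlation surface at fractional lags directly from the
   cross-spectrum (two-stage argmax, 0.1 px then 0.01 px). Three-point
   Gaussian or parabolic peak fits show classic peak locking on smooth
   phase imagery; the upsampled argmax does not.
3. *High-pass prefiltering.* The smooth cell envelope, truncated at
   window edges, drags the peak towards zero; correlating on
   `density - gblur(density, 4 px)` removes it while keeping the
   granular, trackable texture.

Vectors from windows with too little mass (mean density below
0.05 pg/µm²) or ambiguous peaks (primary/secondary ratio below 1.2) are
flagged, outliers are removed by a 3×3 local-median test (threshold 3
robust z, with a small residual floor so noise-free uniform fields are
not over-flagged), vectors that cannot be corroborated by at least three
valid neighbours are dropped, and flagged nodes are infilled by iterated
neighbourhood medians.

Two further choices depart from the most common PIV defaults, each with a
measured rationale:

- *Window size 32 px at 75% overlap* (node spacing 8 px — the same
  spacing as 16-px windows at 50% overlap, with four times the texture
  per window). With ~3 px speckle, 16-px windows carry so few independent
  features that the per-window displacement noise (~0.05 px) integrates
  into spurious mass trends over a 30-frame track; 32-px windows bring it
  to the ~0.01–0.02 px the Lagrangian error budget needs. The field is
  still sampled every 2 µm, far coarser than the 0.7 µm² volumes it
  drives but appropriate for smooth intracellular flows.
- *Multi-frame correlation baselines* (`computeVelocityFields()`,
  default `"auto"`). Intracellular speeds of ~0.2 µm/min move features
  by well under a pixel per 1-min frame, so correlating frames k and
  k+K and dividing by the elapsed time raises the displacement far above
  the correlation noise floor. The automatic rule targets a baseline
  displacement of about half the search radius (capped at 15 frames) from
  a single-interval pilot pass, and a full-width baseline window slides
  inside the movie so late intervals are measured as well as early ones.
  The cost is temporal low-pass filtering of the velocity; for strongly
  unsteady flows set `baseline = 1`.
- *Window deformation* (`deformPasses`, default 1). In rotational or
  shear flow the fast side of a window decorrelates first, dragging the
  peak towards the slow side. A refinement pass warps the second frame by
  the current field and correlates the residual, removing most of this
  gradient bias; a second pass helps at high shear.

**Control volumes.** Square volumes of 0.7 µm² (side ~0.84 µm) are tiled
over the mask's bounding box and kept where their centre lands on the
mask; ids are row-major, so seeding is deterministic. Corners (4 per
volume) are advected by explicit Euler with bilinearly interpolated
velocities; a midpoint (RK2-in-space) option exists but at sub-pixel
per-frame displacements Euler's error is negligible against the
velocimetry error. Volumes whose corners leave the image or whose
polygon self-intersects are truncated at that frame and excluded from
fitting thereafter — re-seeding would mix material identities.

**Mass integration.** The reference path clips the polygon against every
pixel square (Sutherland–Hodgman, compiled) and sums density times exact
coverage; it is exact for the piecewise-constant image model. A second,
independent path intersects horizontal scan lines with the polygon
(exact in x, 256 lines per pixel row in y); the two agree to well under
10⁻³ pg on this pipeline's scales and serve as mutual checks. Degenerate
(zero-area) polygons integrate to 0 pg with a flag rather than an error.

**Growth maps and regions.** Each pixel whose centre falls in a volume's
window-start polygon carries that volume's fitted rate; overlaps resolve
to the nearest seed centre; uncovered pixels are NA. Region statistics
sum the rates of volumes seeded inside the region mask and normalize by
the region's dry mass at the window start (specific growth rate, 1/h).
Sliding windows (default 30 min maps; 120 min windows at 60 min steps
for cell-cycle-style series) re-seed, re-track and re-fit per window.

**Puncta.** A punctum is a connected component of map pixels beyond
±threshold with area ≥ 0.5 µm². The default threshold is 4 times the
robust noise scale (1.4826·MAD) of the map's defined pixels. The
multiplier matters: the map is piecewise constant over control volumes,
so a single noisy volume already exceeds the minimum area, and with
hundreds of volumes per cell a ~2-sigma cut would flag spurious puncta on
essentially every map — including the zero-growth control, which must
come back empty.

## The synthetic generator

`syntheticScene()` / `renderMovie()` emulate the acquisition end to end:
a cell-like disk (radius 7 µm, peak density 1.2 pg/µm², logistic edge of
0.5 µm) multiplied by band-limited granular texture (feature FWHM 3 px,
contrast 0.35 — close to the diffraction-limited speckle a high-NA 100×
system produces at 0.25 µm sampling, and essential: featureless disks
defeat correlation velocimetry), evolved under a prescribed velocity
field (uniform, solid-body rotation, or shear) and source term (uniform
specific growth, or localized co-moving blobs), rendered to OPD at
alpha = 0.18 with 0.5 nm Gaussian OPD noise per frame — small against
the ~200 nm cell signal, as in practice.

Frames are generated by the method of characteristics: every supported
flow has a closed-form flow map, so each frame samples the *initial*
density at exactly back-tracked points (one bicubic interpolation per
frame). An earlier frame-by-frame semi-Lagrangian scheme was abandoned
after the inverse pipeline faithfully reported its accumulated
resampling diffusion as a spurious mass-dependent growth signal; with
exact characteristics, generator error does not compound and total mass
is conserved to ~0.1% over 60 frames for in-frame content. Sources are
applied in material coordinates (blobs co-move with the flow — the
physically sensible choice for cellular structures, and the one that
makes window-start puncta centroids comparable to blob positions).
`fixedCellFixture()` covers the complementary control: a static cell
rigidly translated by Fourier shifting with fresh noise per frame, whose
true growth is identically zero everywhere.

What passing tests on these scenes do show: the pipeline's estimator
chain is unbiased and appropriately uncertain under realistic geometry,
noise, motion and growth scales, with exactly known truth. What they do
not show: robustness to optical artifacts (halo, shading beyond a plane,
phase unwrapping), organelle-scale refractive heterogeneity, focus
drift, or genuinely 3-D motion. Results on real data inherit those
caveats.

## Numerical choices and degenerate inputs

- Pixel (r, c) spans `[(c-1), c] × [(r-1), r]` times the pixel size;
  centres sit at half-integers. All geometry shares this convention.
- Correlation: flat (zero-variance) windows return an invalid flag, not
  an error; fields with fewer than 4 valid vectors abort the frame pair.
  Displacements are clamped to the search radius (8 px default).
- Subpixel refinement steps 0.1 / 0.01 px; the 0.01 px grid sets the
  quantization floor of single-pair estimates.
- OLS fits require ≥ 3 in-window samples; otherwise the estimate is
  flagged invalid and excluded from maps and region sums. The truncation
  frame of an out-of-bounds track still contributes its last mass sample.
- Ties in growth-map rasterization resolve to the nearest seed centre;
  the tiling at seed time is overlap-free by construction.
- A resolution guard warns when 95th-percentile displacements exceed
  half the diffraction-limited resolution (0.48 µm default) per frame.
- Unknown configuration keys are rejected outright; all keys carry units
  in their names.
- Rendered OPD is clipped at zero (detector-like), which slightly skews
  off-cell noise; the plane background fit absorbs the resulting offset.

Problem sizes throughout the tests and the acceptance script — 120 px
(30 µm) frames, ~320 volumes per cell, 31–121 frames, 5–10 replicate
seeds — were chosen as the smallest configurations that still exercise
every stage at realistic scale separation.

## Output formats

Mass stacks and growth maps are written as uncompressed 32-bit float
multi-page TIFFs by a minimal writer included in the package (installed R
TIFF writers only store integer sample formats, which cannot represent
negative rates or densities above 1); `tiff::readTIFF`, Fiji and
tifffile read them directly. NaN marks undefined growth-map pixels.
Velocity fields, tracks, estimates, regions and puncta are plain CSV;
the run manifest (JSON) records the package version, full configuration
and input checksums, and two runs with identical inputs produce
byte-identical trees.

## Known limitations

- 2-D only: axial motion and mass flux are assumed negligible.
- Velocity temporal resolution trades against precision via the
  correlation baseline; rapidly fluctuating flows need `baseline = 1`
  and accept noisier rates.
- Segmentation is threshold-based bookkeeping; cells touching other
  cells need user-supplied masks.
- The OLS standard error reflects residual scatter around a linear mass
  trend, not velocimetry bias; a persistent tracking error shows up as
  rate bias, which the fixed-cell control quantifies but the per-volume
  error bars do not contain.
- Topology changes of control volumes (splitting/merging) are not
  modelled; strongly deforming regions lose volumes to the
  simplicity/bounds checks instead.
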