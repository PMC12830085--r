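---
title: "Models and methods behind octra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind octra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

octra processes series of cellular-resolution retinal OCT volumes: it
registers repeated acquisitions of the same retinal patch, averages them
hierarchically to suppress speckle, quantifies the resulting image quality,
simulates a wavefront-sensorless adaptive-optics (WSAO) correction loop,
segments the ganglion cell complex (GCC), and counts retinal ganglion cell
(RGC) somas. Because validated in vivo data with voxel-level ground truth do
not exist, the package ships a synthetic phantom generator whose every
placement is recorded; all accuracy claims in the test suite are made against
that ground truth and should be read as statements about the phantom, not
about any particular instrument.

## Conventions

Volumes are arrays indexed `(b, z, x)`: B-scan (slow lateral) index, depth,
A-scan (fast lateral) index. A B-scan is a `(z, x)` plane; an en face image is
a `(b, x)` plane. All indices are 1-based and ranges are inclusive, following
R convention. Intensities are linear (not log-compressed), finite,
non-negative doubles; files store them as 32-bit IEEE floats. Several metrics
(speckle contrast in particular) are scale-sensitive, so inputs that were
log-scaled by an instrument must be linearized first. Default pitch is the
native grid of a 310 µm field sampled by 512 A-scans (310/512 ≈ 0.605 µm
lateral) with a configurable 1 µm axial pitch.

## The synthetic phantom

The phantom stacks smooth reflectivity bands for the retinal layers (vitreous,
RNFL, ganglion cell layer, IPL, INL, ONL, RPE), places hyperreflective
soft-edged ellipsoidal somas in the ganglion cell layer by dart throwing
(diameters uniform in 5–10 µm, the mouse RGC range; centres at least one
diameter apart; planar density 4407 cells/mm² by default, a mid-superior
retina value), and stamps a regular mosaic of hyporeflective discs into the
RPE band (nuclei surrounded by reflective melanosome-rich cytoplasm). The
soma/neuropil reflectance ratio is not a measured quantity; the default
(soma 1.3 against a 0.25 ganglion-cell-layer band) was chosen so that single
speckled volumes hide the mosaic while averages of a few dozen volumes
resolve it clearly.

Speckle is multiplicative on reflectivity. Volume `v` receives

I_v = R · |α·A + √(1−α²)·B_v|²,

where `A` is one shared and `B_v` a fresh unit-variance circular complex
Gaussian field. The speckle factor has unit mean, a single volume over
constant reflectivity is fully developed speckle (exponential intensity,
contrast `C = σ/μ = 1`), and averaging `N` fully decorrelated volumes gives
`C ≈ 1/√N`. Note that with this mixture the *field* correlation between
volumes is α², so the *intensity* correlation is α⁴ (the squared field
correlation, a standard property of circular Gaussian speckle); the property
tests assert α⁴. α is an effective stand-in for the biological decorrelation
("organelle motility") that real tissue exhibits: soma interiors decorrelate
faster (default α = 0.2) than the structural surround (default α = 0.6), so
averaging converges to clean homogeneous hyperreflectivity inside cells while
the surround retains a static residual texture. The phantom does **not**
model vascular shadowing, coherent point-spread-function speckle, eye motion
during a B-scan, or log compression; conclusions from passing tests transfer
to real data only to the extent those effects do not dominate.

Motion is sampled uniformly within configurable ranges — defaults ±4 px rigid
B-scan-plane (XZ) shift, ±1° rotation, ±3 px en face (XY) drift, ±2 px
per-B-scan axial jitter — large enough to defeat naive averaging yet inside
the registration search windows. Sub-voxel motion is applied by linear
interpolation, and voxels sourced from outside the grid are flagged invalid
rather than zero-filled so that averaging never ingests fabricated
intensities. Longitudinal degeneration reuses one baseline mosaic and thins
it binomially and *nested* (survivors at a timepoint are a subset of the
previous timepoint's survivors), so expected counts follow the survival
schedule exactly.

## Three-stage registration and hierarchical averaging

Volumes are processed in batches (default six). Stage 1 estimates a rigid XZ
transform per volume from side projections (mean over the central 60
B-scans) against the batch's first volume: translation by sub-pixel phase
correlation, rotation by a discrete scan (±2° in 0.1° steps, with parabolic
sub-step refinement) maximizing windowed normalized cross-correlation.
Stage 2 estimates sub-pixel en face translations by phase correlation of
standard-deviation projections over depth (full depth by default — the RPE
mosaic is a strong en face anchor; configurable). Stage 3 reorganizes the
batch into a B-scan-major stack (all first B-scans, then all second B-scans,
…), aligns each frame to its already-aligned predecessor by per-column
(A-line) cross-correlation with a ±8 px search, averages the per-column
displacements of columns whose normalized correlation peak reaches 0.3, and
accumulates the shifts along the stack. Aligned batches are averaged with
mask weighting, and rounds repeat on the batch averages until one volume
remains (a trailing partial batch of at least two is processed as its own
batch; a leftover singleton passes through).

Several numerical choices matter in speckled data and are worth stating
explicitly:

* **Windowing and band-limiting.** Phase correlation whitens the spectrum, so
  in projections of partially decorrelated speckle every noise-dominated high
  frequency votes as loudly as the structure. Images are Hann-windowed and
  the whitened cross-power spectrum is weighted by a Gaussian low-pass
  (σ = 0.15 cycles/px) before the peak search; sub-pixel refinement evaluates
  the same spectrum on a 0.02 px grid around the integer peak.
* **Rotation scoring.** The angle scan scores normalized cross-correlation on
  projections pre-smoothed with σ = 1.5 px. Scoring unsmoothed images is
  biased away from zero: resampling smooths speckle at every trial angle
  except 0, so any nonzero angle would enjoy a noise advantage.
* **Correction gating.** Stage-1/stage-2 estimates are discarded (zero
  transform) when the two projections' peak normalized correlation falls
  below 0.35, and a stage-3 frame shift requires at least a quarter of the
  columns to pass the validity check. Projections that share no real
  structure otherwise receive random warps whose interpolation measurably
  *lowers* speckle contrast below the 1/√N law.
* **Drift control.** Chained frame-to-frame alignment accumulates a
  random-walk error that slowly bends the volume in depth. The cumulative
  stage-3 shifts are therefore detrended with a reflect-padded running median
  (window 8 × batch size + 1 frames): per-volume offsets and per-B-scan
  jitter alternate at the interleaving period and survive, while the slow
  walk (and real anatomy, which must not be "corrected") is removed.

**Accuracy floor.** On the default phantom the stages recover synthetic
motion to roughly 0.25 px (stage-1 translation), 0.15° (rotation), 0.2–0.3 px
(stage-2), and 0.5 px relative axial alignment. The stage-2 floor is
structural, not an estimator defect: the standard-deviation projection is a
nonlinear statistic of speckle, and under any sub-pixel lateral shift of the
volume the neighbouring-column decorrelation distorts the SD texture and
biases its apparent shift by a few tenths of a pixel. The package's
operation-level phase correlation reaches 0.05 px on images shifted as
images; the 0.1 px figure simply does not survive the SD-of-speckle
projection, and the corresponding acceptance assertion is expected to fail
on this phantom class. Composite full-motion experiments are instead
validated by the end-to-end invariant (residual inter-volume displacement
below 0.5 px) and by soma-edge sharpness: at 36 volumes the registered
hierarchical average's en face Tenengrad exceeds the unregistered average's
by ≥ 50% (the en face readout is a 5-slice mean slab at the soma band — a
thick slab would reward misalignment by blending tilted-RNFL light into the
unregistered image).

## Image-quality metrics

Tenengrad (sum of Sobel gradient magnitudes) and local contrast maps use
non-overlapping 20 × 20 px patches by default, dropping trailing partial
patches. The contrast map uses the sample (N−1) standard deviation, as the
map is conventionally defined; scalar speckle contrast `C = σ/μ` uses the
population SD. Improvement ratios are ratios of map means. SSIM uses an
11 × 11 Gaussian window (σ = 1.5), K1 = 0.01, K2 = 0.03, dynamic range taken
from the reference image, evaluated where the window fits entirely inside
the image. Line profiles sample at unit arc-length spacing with bilinear
interpolation so the same coordinates can be reused across a series. Quality
curves against the number of averaged volumes are fitted with a one-phase
exponential `y(N) = plateau + (y0 − plateau)·exp(−(N−1)/τ)`, parameterized in
`N − 1` so `y(1) = y0` exactly; the Levenberg–Marquardt fit restarts from
three τ scales, and constant data are flagged unidentifiable rather than
fitted.

## Simulated sensorless correction

The WSAO simulation images an en face reflectance scene through an aberrated
pupil: Zernike modes Z4–Z15 (Noll indexing and normalization, unit RMS per
unit coefficient), incoherent circular convolution with the pupil's intensity
PSF, and multiplication by the Strehl ratio. The Strehl factor models the
confocal double-pass coupling loss; without it, convolution preserves mean
brightness exactly and the brightness metric would be blind to aberration.
The optimization reproduces a single sequential round: for each mode from Z4
to Z15, brightness is evaluated over nine trial values spanning ±1 rad, the
grid argmax is refined by a three-point parabola, and the refined value is
kept only when it actually measures brighter — so the running best brightness
never decreases. Mode cross-talk is inherent to sequential optimization and
no second round is performed. For random aberrations with per-mode
coefficients within ±0.5 rad, one round removes well over half the RMS
wavefront error in ≈95% of trials; the residual failures are draws whose
initial error is already near the grid resolution.

## GCC segmentation and soma counting

Segmentation is seeded: on the central B-scan, user marks for the anterior
RNFL intensity peak and the posterior IPL valley are snapped to the strongest
local extrema of the vertical derivative (Gaussian enhancement σ = 1 px,
min–max normalization, forward difference along depth — marks are snapped on
the derivative, not raw intensity) within ±2 px. Boundaries are traced
column-by-column within ±2 px of the neighbouring column, median-smoothed
over 5 columns, and propagated frame-to-frame by surface growing, each
frame's search centred on the previous frame's boundary. Columns whose chosen
extremum falls below a quarter of the seed's magnitude are flagged as
tracking losses, and a frame losing more than 20% of its columns aborts with
a diagnostic. Thickness is `(ipl_z − rnfl_z) ×` axial pitch, reported as the
map mean. Since both boundaries are localized on the same forward-difference
convention, the half-voxel localization offsets cancel in thickness.

Counting is an automated surrogate for manual z-stack grading and enforces
the same printed criteria: hyperreflectivity (intensity percentile threshold
inside the layer band, default the 90th), persistence across at least three
consecutive depth frames, in-plane equivalent diameter within 5–10 µm, and
roundness (minor/major axis ratio ≥ 0.6). Components come from 6-connected
3-D labelling above threshold. The equivalent diameter adds a half-pixel
boundary correction, because the sampled footprint of a thresholded digitized
disc stops about half a pixel inside its true rim — without it the smallest
genuine 5 µm somas measure ≈4.7 µm and are wrongly rejected. The surrogate is
validated only against phantom truth (precision and recall ≥ 0.9 on a
36-volume average at the default density) and is not claimed to replicate a
human grader on instrument data. Densities use the 310 × 310 µm field
(36 µm/deg); percent change `(baseline − value)/baseline × 100` and
concordance `a/b × 100` are exact and rounded to integer percent only in
summary tables.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the full pipeline at reduced
grids chosen to keep each experiment to a few minutes on one CPU while
preserving the regimes that matter: speckle-law and averaging experiments on
64 × 128 × 128 constant phantoms (36 volumes) and 32 × 96 × 96 structured
phantoms (72 volumes); registration recovery on 64 × 128 × 256 phantoms
(rotation needs the lateral lever arm; ten seeds per stage); soma detection
on a ≈50-cell 176 × 128 × 176 field; and the longitudinal experiment at the
full field scale (310 × 310 µm, ≈424 baseline cells) with survival
fractions matching the reference longitudinal counts. Every stochastic
step is seeded; `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
reproduces the numbers end to end.

## Known limitations

* Registration is rigid per stage; deformable motion, intra-B-scan
  distortion, and real-time operation are out of scope.
* The stage-2 sub-pixel floor (≈0.2–0.3 px) discussed above.
* The phantom's speckle is a voxel-wise field mixture, not a coherent PSF
  simulation; its α parameters are effective, not physically calibrated.
* The soma detector assumes averaged input; single-volume speckle defeats it
  by design.
* Segmentation is user-seeded by construction; no automatic seed detection is
  attempted.
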