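# octra

Registration, averaging, and quantification for cellular-resolution retinal
OCT.

Mouse retinal ganglion cell (RGC) somas are 5–10 µm across — at the scale of
a single OCT speckle grain — so in a single adaptive-optics OCT volume the
cellular mosaic is invisible under fully developed speckle (contrast
`C = σ/μ = 1`). Because speckle decorrelates between repeated acquisitions
while the tissue does not, registering and averaging many volumes of the same
retinal patch suppresses it towards `1/√N` and makes individual somas
countable in vivo. octra implements that processing chain for researchers
working on cellular-resolution retinal imaging and longitudinal
neurodegeneration models:

* **Three-stage volume registration** — (1) rigid B-scan-plane (XZ)
  alignment of side projections (phase correlation + a discrete rotation
  scan), (2) sub-pixel en face (XY) phase correlation of
  standard-deviation projections, (3) per-B-scan axial alignment by
  A-line-wise cross-correlation along the interleaved B-scan stack — followed
  by **hierarchical batch averaging** (batches of six, repeated on the batch
  averages until a single volume remains).
* **Image-quality metrics**: patchwise Tenengrad `T(P) = Σ|∇I|` (Sobel) and
  local contrast `σ(P)` maps, improvement ratios, speckle contrast
  `C = σ/μ`, SSIM, line-profile Pearson correlation, and one-phase
  exponential fits `y(N) = plateau + (y0 − plateau)·e^{−(N−1)/τ}` of
  quality-vs-averaging curves.
* **Simulated wavefront-sensorless AO**: Zernike-aberrated (Noll Z4–Z15)
  imaging of an en face scene with Strehl-weighted incoherent convolution,
  and a single sequential modal-optimization round maximizing image
  brightness.
* **Seeded GCC segmentation**: derivative-based boundary tracing from user
  marks, surface growing across frames, voxel-wise ganglion-cell-complex
  thickness maps.
* **Soma counting**: 3-D connected components with the manual-grading
  criteria enforced automatically (hyperreflectivity, ≥3 consecutive depth
  frames, 5–10 µm equivalent diameter, roundness), densities per mm², and
  longitudinal percent-loss summaries.
* **A synthetic phantom generator** (layered retina, soma mosaics, partially
  decorrelated speckle, rigid/lateral/axial motion, longitudinal cell loss)
  with full ground truth, so every stage is testable against known answers.

See `vignettes/oct-pipeline-methods.Rmd` for the models, parameter defaults,
and numerical design choices.

## Worked example

Simulate a 12-volume series of a 48 × 128 × 128 phantom (one batch field of
view ≈ 29 × 77 µm), corrupt it with motion, then register, average, and
quantify:

```r
library(octra)

spec   <- phantom_spec(shape = c(48, 128, 128), seed = 1)
truth  <- make_phantom(spec)                      # ground truth: 8 somas
series <- add_speckle(truth, 12, seed = 2)
moved  <- apply_motion(series, spec, seed = 3)

avg <- hierarchical_average(moved$series, run_config())$volume

round(c(single   = speckle_contrast(series$volumes[[1]]$data[, 36:52, ]),
        averaged = speckle_contrast(avg$data[, 36:52, ])), 3)
#>   single averaged
#>    1.308    0.546

cells <- detect_somas(avg, band = c(36, 52))
nrow(cells)                                       # 8 of 8 truth cells found
#> [1] 8
count_density(nrow(cells), fov_um = dim(avg)[c(1, 3)] * avg$pitch_um[c(1, 3)])
#> <count_summary> 8 cells over 0.0023 mm2 = 3552 cells/mm2

surf <- grow_surface(avg, aline_x = 64, peak_z = 24, valley_z = 64)
mean(surf$thickness_um)                           # true GCC thickness: 40 um
#> [1] 39.8
```

The speckle contrast of the ganglion-cell band drops from 1.31 (single
volume; above 1 because reflectivity structure adds to fully developed
speckle) to 0.55 after the registered 12-volume average; all 8 ground-truth
somas are recovered, and the segmented GCC thickness lands within 0.2 µm of
the 40 µm truth.

A command-line front end wraps the same functions
(`inst/cli/octra.R simulate | register | metrics | wsao | segment | count`),
each subcommand taking `--config`, `--seed`, `--out`.

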