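---
title: "Quantifying subcellular organization in rod-shaped bacteria with rodmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subcellular organization in rod-shaped bacteria with rodmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodmap)
```

# Scope and model

`rodmap` measures how cargo (e.g. carboxysomes), a positioning ATPase
(e.g. McdA), and the nucleoid are organized inside rod-shaped bacterial
cells imaged by multi-channel fluorescence microscopy. The pipeline runs
on an `ImageStack` (time x channel x row x column, with a physical pixel
size) and a per-cell label map, and produces per-cell tables for six
quantities:

* **Focus detection and intensity.** Spots are detected per cell with an
  unsharp mask, a Gaussian blur, and a single-scale Laplacian of Gaussian
  at $\sigma = d/(2\sqrt2)$ for blob diameter $d$ (default $d = 3$ px,
  quality threshold 80). A detection's intensity is the sum of *raw*
  pixel values within a circle of radius $2r$ around it, $r = d/2$.
* **Tracking and confinement radius.** Detections are linked
  frame-to-frame by a gated linear assignment with squared-distance cost
  (gate 7.5 px), then segment ends and starts are gap-closed (gate
  4.5 px, at most 2 missing frames). The confinement radius of a track is
  the mean distance of its first ten localizations from their centroid —
  a deliberately simple mobility proxy that needs no diffusion model.
* **Nucleoid compaction.** Per cell, the cytoplasmic intensity $b$ is the
  mean of a Gaussian fitted to the histogram of the inner-rim pixels
  (rim = mask minus its erosion by `rimDepthPx`, default 2); after
  subtracting $b$ (clipped at 0) and blurring (sigma 66 nm), Yen's
  threshold on the in-mask histogram delimits the nucleoid, and
  $s_\mathrm{comp} = 1 - A_\mathrm{nuc}/A_\mathrm{cell}$.
* **Oscillation score.** Per cell, intensities are min-max normalized,
  $I_n = (I - I_\min)/(I_\max - I_\min)$, and the score is the fraction
  of pixels with $I_n < 0.5$ (strict). Polarized or pole-to-pole
  oscillating distributions score high; diffuse ones score near 0.5. The
  quotient makes the score invariant under positive affine intensity
  transforms, so gain and offset drop out.
* **Cell-frame density maps.** Each localization is re-parameterized into
  $(r_\mathrm{rel}, l_\mathrm{rel}, \phi)$: perpendicular distance from
  the midline over the cell width, arc-length fraction along the midline,
  and, in the polar caps, the angle from the outward midline tangent.
  Counts and per-cell bin areas are summed across cells, optionally
  folded fourfold (left/right x head/tail), and converted to probability
  density $(\sum C/\sum A)/C_\mathrm{tot} \times n_\mathrm{cells}$ in
  $\mu m^{-2}$, so that $\sum (\text{density} \times \text{area}) =
  n_\mathrm{cells}$ exactly.
* **Pearson colocalization** over in-mask pixel pairs (per cell) or whole
  fields, with an optional viability gate on a chlorophyll channel.

Registration aligns every frame to the first by integer-pixel
cross-correlation of the reference (phase-contrast) channel, applying the
same shift to all channels of that time point.

# The synthetic-scene generator

Real acquisitions of this kind are rarely redistributable, so every stage
is validated against `simulateScene()`, which renders a field of
spherocylindrical cells (~1 um wide, 2.5-4 um long, 60 nm/px) with full
ground truth fixed *before* noise is drawn:

* **Foci** are isotropic Gaussians (PSF sigma 120 nm = 2 px, matched to
  the 3 px detector scale) moving on confined random walks. The walk uses
  a Metropolis hard wall: steps that would leave the confinement disk are
  redrawn. A folding/reflecting rule was rejected because its stationary
  law degenerates to radially-uniform when the step size exceeds the
  radius, whereas the hard wall is uniform on the disk at every step
  size, so the mean centroid distance of a long walk is $2R/3$ exactly.
* **Nucleoids** are the cell mask compressed along a principal axis to a
  target area fraction, built inside a core inset up to 2 px from the
  boundary — nucleoids do not abut the membrane, and the rim-background
  method presumes a cytoplasmic rim. The DAPI-channel blur is 66 nm
  sigma, the diffraction scale at blue emission; the region's pixel count
  is matched to the requested fraction exactly (per-pixel threshold
  targeting), and the truth is recorded pre-blur.
* **Protein patterns** are `polar_gradient` (exponential decay from one
  pole, the pole alternating with a phase series), `diffuse`, or
  `puncta`.
* **Drift, correlation, noise.** Integer per-frame stage drift;
  channel pairs with an exact population correlation; background 100,
  Gaussian read noise sigma 5 by default (high SNR so failures indicate
  bugs, not noise), optional Poisson shot noise.

What the generator does **not** emulate: 3-D optics and defocus,
chromatic offsets between channels, photobleaching kinetics (beyond the
per-column kymograph normalization that removes it from visualizations),
cell growth and division, and segmentation-quality pathologies of real
phase contrast. Passing tests therefore demonstrate the correctness of
the measurement chain, not robustness to every real-world artifact.

# Numerical and design choices

* **Coordinates** are 0-based with integer coordinates at pixel centers;
  nearest-pixel lookups round half up so results are invariant under
  integer translation.
* **Midline.** The mask is thinned (Zhang-Suen), spurs shorter than half
  a cell width are pruned, the longest geodesic path is kept, smoothed
  with a short moving average, and extended along its end tangents to the
  boundary (0.25 px stepping). Length is the arc length of this
  pole-to-pole polyline; width is twice the mean perpendicular
  ray-cast distance to the subpixel boundary over the cylindrical part.
  Near-round cells fall back to the principal axis through the centroid.
* **Cylindrical vs polar.** For the coordinate system the midline is
  trimmed by half a width at each end; projections beyond the trimmed
  ends are polar. $\phi$ lies in $[0, \pi/2]$ with a signed `side`, so
  the fourfold fold is a real symmetry operation, and the bin table
  records each bin's symmetry class for audit.
* **Bins** default to 3 radial rings x 8 longitudinal segments
  (cylindrical) and 3 rings x 4 sectors per polar cap, per side, with an
  open outermost radial edge so boundary quantization cannot escape the
  grid; boundary values fall to the lower-index bin.
* **Width normalization** of $r_\mathrm{rel}$ uses the *per-cell* width,
  so cells of different calibers share a frame of reference.
* **Linking** pads the gated cost matrix with per-detection "no link"
  alternatives priced just above the gate, and solves the square problem
  with a shortest-augmenting-path assignment solver (oracle-tested
  against exhaustive enumeration). Linking distances stay in pixels;
  micrometers appear only in reported statistics.
* **Yen's threshold** is computed on a 256-bin histogram for continuous
  input and exactly on integer levels for 8-bit-like input, where it is
  tested for exact agreement with an exhaustive criterion search.
* **ROUT outliers** use the constant model: median center, robust scale
  from the 68.27th residual percentile inflated by $n/(n-1)$, t-tail
  P-values, and a Benjamini-Hochberg step at $Q = 1\%$ (the method's
  conventional default; the rate is exposed). Fewer than five values are
  returned untouched, flagged.
* **Quantiles** everywhere use linear interpolation (R type 7).
* **Storage.** Stacks are written as multi-page 32-bit TIFF with a JSON
  sidecar (layout, pixel size, frame interval, intensity scale); reads
  fail loudly on missing metadata or page-count mismatches.
* **Frame interval** is carried as metadata and never assumed; kymograph
  columns are whatever time points the stack provides.
* **Interface.** The package is driven from R: exported functions plus
  `runExperiment()` cover simulation, registration, segmentation,
  detection, tracking, nucleoid, oscillation, colocalization, and the
  density map, each stage also callable on its own. Tables are plain
  data.frames ready for `write.csv()`.

# Problem sizes

The test suite and the acceptance script run scenes of 3-5 cells (up to
10 frames), 100 single-cell detection fields, 1,000 random tracks for
the confinement oracle, and 10^4-pixel masks for correlation recovery —
sizes chosen so the full suite completes in well under a minute while
every statistical bound retains comfortable margins.

# Known limitations

* $s_\mathrm{comp}$ carries method-intrinsic biases at extreme nucleoid
  area fractions: Yen's criterion cuts just above the background mode, so
  the blur skirt around a *compact* nucleoid is counted as nucleoid
  (overestimating $A_\mathrm{nuc}$ by roughly perimeter x ~1 px), while a
  nucleoid filling ~80% of the cell contaminates the rim histogram and
  inflates the fitted background (underestimating $A_\mathrm{nuc}$). At
  1 um x 4 um cell size and 60 nm pixels these biases can reach ~0.1-0.2
  at area fractions 0.2 and 0.8; mid-range fractions are recovered
  closely and the ordering across fractions is always preserved, which is
  what cross-condition comparisons rely on. The acceptance suite states
  the strict +-0.05 recovery check and the test output records where it
  fails.
* Integer-pixel registration and detection (no subpixel refinement by
  default): adequate because intensity integration is defined on raw
  pixels and downstream statistics tolerate <=0.5 px localization error;
  quadratic peak refinement can be added behind the detector interface.
* The segmentation backend is pluggable but the built-in one is a simple
  inverted threshold intended for synthetic phase contrast; real data
  should come with labels from a dedicated segmenter, passed as the
  `external` backend or an override label map.
* Tracking has no motion model and no split/merge events; it reproduces a
  two-stage link/gap-close design, not a Kalman tracker.
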