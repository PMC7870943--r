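---
title: "Quantifying droplet-printed microbial communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying droplet-printed microbial communities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printarray)
```

## The system and the measurement problem

Droplet printing deposits ~110-µm agarose droplets, each seeded with ~70
bacterial cells (10^8 cells mL⁻¹ in the bioink), onto a square lattice; the
droplets fuse into a single gelled array in which each founder cell grows
into a clonal microcolony of median diameter 15 µm (quartiles roughly
10–21 µm). Printing two fluorescently labelled genotypes in different
per-droplet layouts imposes *genetic mixing* at the micron scale, and the
ecological outcome of competition (who grows, who is killed) depends on that
spatial structure. `printarray` implements the quantification side of such
experiments: turning two-channel micrographs or confocal stacks into colony
tables, print geometry, segregation indices and outcome metrics — and, since
raw imagery is not required, a seeded synthetic-scene generator that
emulates the printed arrays end to end.

## The segregation index SI(h)

Every pixel of a two-channel image is assigned a genotype by thresholding
each channel separately with Otsu's method: A if only channel 1 exceeds its
threshold, B if only channel 2 exceeds, NONE otherwise. For a focal A/B
pixel $i$, the local index over a square neighbourhood of half-width $h$
pixels is

$$s_i(h) = \frac{1}{N_i(h)} \sum_{j=1}^{N_i(h)} g_i(j), \qquad
g_i(j) = \begin{cases} 1 & \text{pixels } i, j \text{ are kin} \\
0 & \text{otherwise,} \end{cases}$$

where $N_i(h)$ counts the A/B pixels within $h$ rows or columns of $i$
(NONE pixels are never counted). The global index is the arithmetic mean
over all $M$ focal pixels,

$$SI(h) = \frac{1}{M}\sum_{i=1}^{M} s_i(h),$$

ranging from ~0.5 (fully mixed at scale $h$) to 1.0 (a single genotype).
Spans convert between pixels and micrometres via the imaging resolution of
1.515 µm/px, so the standard spans 5, 10, 20, 50 and 100 px correspond to
7.6–151.5 µm.

Decisions the definition leaves open, and how this package resolves them:

* **Self-inclusion.** Whether the focal pixel counts among its own
  neighbours is unstated. The default includes it, which guarantees
  $N_i \ge 1$ so $s_i$ is defined everywhere; `include_self = FALSE` gives
  the other variant. At $h \ge 20$ px the difference is far below every
  tolerance used here.
* **Background pixels.** Only the both-channels-bright case is explicitly
  NONE in the definition; pixels bright in neither channel are also NONE
  here, since background carries no genotype and only "A- or B-type" pixels
  are ever counted.
* **Borders.** Neighbourhoods are clipped at the image edge and $N_i$
  counts only existing pixels.
* **Implementation.** `global_si()` uses summed-area tables (exact integer
  counts, linear time); `global_si_bruteforce()` is the quadratic
  double-loop oracle, and the test suite requires exact agreement between
  the two on random masks up to 64×64.

Rendering the idealised *reference image* of a printing map (filled disks
labelled by droplet assignment, per-pixel Bernoulli draws inside MIXED
droplets) gives the theoretical SI of a layout. The 7×8 segregated-halves
reference yields SI ≈ 0.944 at the 100-µm span — the band of width $2h$
around the single A/B interface averages $s \approx 3/4$, giving
$1 - \tfrac{1}{4}\cdot\frac{2h}{\text{extent}} \approx 0.943$ — and the
per-pixel 1:1 mixed reference yields 0.500. Measured prints sit *above*
their reference at spans below the microcolony diameter (colonies are
clonal patches, so there is no mixing within ~15 µm) and converge to the
reference at larger spans; comparisons between measured and reference
profiles are therefore most meaningful at the 100-µm span, and that is the
span at which the end-to-end recovery tests assert agreement (within 0.03).

## 2D segmentation

`segment_microcolonies_2d()` works on the channel-sum image: Gaussian
smoothing at the colony scale (default σ = 2 px), Otsu foreground
thresholding, subtraction of dark inter-colony ridges, then a morphological
watershed seeded from smoothed-intensity regional maxima (minimum
prominence 10 % of the dynamic range, via `EBImage::watershed`, which
floods deterministically), and removal of components below 10 px². The
ridge detector is the 2D specialisation of the 3D machinery below: the
signed largest-magnitude Hessian eigenvalue at the expected gap scale
(default 3 px), thresholded at the 90th percentile of its positive values.
Defaults are scale-matched to 15-µm colonies at 1.515 µm/px and all are
exposed as arguments. Whether the original analysis thresholded channels
separately or combined is unstated; combining them makes segmentation
genotype-blind, which is the property the downstream metrics need.

Per-colony features come from unweighted second central moments:
equivalent-ellipse major/minor axis lengths, orientation from the principal
axis (degrees in [−90, 90), counter-clockwise from +x in the screen frame),
centroid in µm (origin at the top-left pixel centre), area, and mean
brightness per channel. A variance of $\text{px}^2/12$ is added per axis so
single-pixel labels have finite extent.

## 3D segmentation

A plain intensity threshold (`rough_threshold()`, Otsu or absolute)
separates bright colony-bearing regions from background but fuses closely
packed colonies. To split them, `hessian_separator_mask()` convolves the
stack with a Gaussian of physical scale σ (default 3 µm, the expected
inter-colony gap), converted per axis to voxels so the filter is physically
isotropic on anisotropic voxels (1.515 µm laterally vs 2.73 µm axially),
builds the 3×3 Hessian per voxel from Gaussian-derivative convolutions, and
orders its eigenvalues by magnitude $|\lambda_1| \ge |\lambda_2| \ge
|\lambda_3|$. Voxels with *signed* $\lambda_1$ above a threshold (default:
90th percentile of positive values) are dark ridge-like separators — blobs,
sheets or tubes darker than their surroundings. Comparing $\lambda_1$
signed rather than by magnitude means bright blob interiors (where
$\lambda_1 \ll 0$) are never flagged.

The combination step contains a genuine ambiguity: combining the rough mask
with the $\lambda_1 > \tau$ mask by a voxelwise AND would keep only the
separators, the opposite of the stated goal of isolating colonies. The
default therefore carves the separators out of the rough mask
(`final = rough AND NOT separator`), which is the reading consistent with
splitting packed colonies; `keep = "separators"` selects the literal
reading. Components are labelled with 26-connectivity. Tests verify that
the final mask is always a subset of the rough mask, that eigenvalues agree
with direct symmetric diagonalisation, that touching synthetic spheres
(one rough component) split into two, and that counts are unchanged when
the z-axis is resampled with σ held fixed in µm.

## Print geometry

* **Centre and size.** The centre is the mean colony position. The side
  length of a (nominally square) print comes from the mean radial distance
  $\bar r$ via $L = 6\bar r / (\sqrt2 + \ln(1+\sqrt2))$ — the exact
  inversion of the expected centre-to-point distance of a uniformly filled
  square. On uniform squares with 1000 points the estimator's bias is below
  2 % (tested over 50 seeds).
* **Isolation.** Colonies beyond `margin_factor` × $L\sqrt2/2$ (the
  half-diagonal with 15 % slack by default; the threshold value is a
  package choice, chosen to accept the print's corners while rejecting
  distant debris) are removed, the centre recomputed, and the threshold
  re-applied once.
* **Registration.** The convex hull's radial profile is resampled onto
  $N = 360$ regular polar angles by ray-casting from the centre onto the
  hull polygon (the polygon's radial support function — markedly more
  accurate than interpolating between hull vertices, which limits phase
  recovery to a few degrees). After mean subtraction, the print rotation is
  the phase of the DFT of $d(\varphi)$ at wavenumber 4:
  $\theta = \tfrac14\big(\pi - \arg \sum_n d(\varphi_n)
  e^{-i 8\pi n/N}\big)$, reported in [−45°, 45°) — the descriptor has the
  square's 90° symmetry. Positions are then rotated about the centre to
  axis-align the print, and the extent is the registered bounding box. The
  sign convention is fixed by the recovery contract (tests require
  $|\hat\theta - \theta_{\text{true}}| < 1°$ mod 90° for rotations drawn
  over [0°, 360°)), not by any convention agreement.
* **Neighbours.** Delaunay triangulation (via `deldir`) defines neighbour
  pairs; colonies on the outer convex hull are excluded, and only edges
  with *both* endpoints interior enter the reported distance distribution
  (the stricter of the two readings of excluding boundary colonies).
  Square-lattice inputs are degenerate for Delaunay, so lattice tests
  jitter positions by 0.1 µm and accept either diagonal.

## Outcome metrics

Frequency is the abundance share $f = A_a/(A_a + A_b)$ and productivity is
the ratio $p = A_a/A_S$ to a *matched no-interference control*, on any
common basis (2D area, 3D volume, cell counts, CFU). The control abundance
$A_S$ must always be supplied explicitly — it is an experimental design
choice and is never inferred. Flow-cytometry gating keeps the central 90 %
box of forward/side scatter (the "core of the population"; the box-quantile
form is a package choice — simple, deterministic, and faithful to the
purpose of minimising count biases), splits events at fluorescence
2^9.5 ≈ 724, and counts the first 3000 gated events in acquisition order.
Doubling time is $\ln 2$ over the least-squares slope of ln OD against time
restricted to the OD 0.2–0.7 window.

## The synthetic-scene generator

`render_scene()` emulates the study conditions so that every stage has
ground truth: per-droplet founder cells are Poisson with mean = density ×
spherical droplet volume (69.7 at the defaults — deterministic counts are
available via `cells_exact` for exact tests), positions are uniform over
the droplet footprint, genotypes follow the printing map (per-cell
Bernoulli inside MIXED droplets), and each cell becomes a disk (or sphere)
colony whose diameter is log-normal with median 15 µm and `sdlog` 0.55 —
chosen once so the quartiles (≈10.4 and 21.7 µm) match the reported
asymmetric 10–21 µm spread on positive support. Droplets sit on a square
lattice at pitch = diameter (tangent disks; the pitch is configurable
because packed arrays could equally be modelled with hexagonal offsets).
The canvas keeps a two-droplet-diameter background margin; whole-print
rotation is applied about the print centroid; debris colonies land 2–2.5
print side lengths away, which is what makes exact debris/print separation
a fair test of the radial threshold. Noise is background + linear gradient
+ additive Gaussian, truncated at zero. One integer seed drives a
hierarchical per-droplet stream, so scenes are bit-reproducible and
droplet substreams do not interact.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: optical blur and the microscope PSF, intensity
falloff with depth, colony shape irregularity and lobed growth,
chemical interactions between genotypes (killing, autoinduction — outcomes
are imposed through the map, never simulated), and droplet packing
distortions. Recovery results on synthetic scenes are a check of the
measurement machinery, not of biology.

## Problem sizes and numerical choices

The test suite and the analysis scripts run the full 7×8 / 110-µm / 1.515
µm-per-pixel conditions wherever a single scene suffices (reference-mask SI
values, end-to-end SI recovery, registration on dense prints). Multi-seed
property sweeps use reduced sizes chosen to keep the whole suite quick on a
laptop while leaving the statistics comfortably inside their tolerances:
composition-recovery runs use a 3-µm pixel and 3×10⁷ cells mL⁻¹ (about 21
founders per droplet), geometry sweeps skip image rendering entirely
(`render = FALSE`) and work on the ground-truth point sets, and 3D scenes
use ~40³-voxel stacks. Tolerances asserted in tests: SI oracle agreement
exact (1e−12), eigenvalue agreement 1e−9, registration 1° mod 90°,
side-length bias 2 %, end-to-end SI 0.03 at the 100-µm span, composition
recovery ±0.05 on the mean over 10 seeds.

Degenerate inputs are contracts, not surprises: blank images segment to
zero labels; non-finite pixels are errors; constant channels make Otsu
undefined and require explicit thresholds; all-NONE masks make SI undefined
(M = 0) and error; collinear point sets refuse triangulation and
registration; a radial threshold that removes every colony signals
misconfiguration rather than returning an empty print.

## Known limitations

* The side-length formula assumes square prints; rectangular 7×8 arrays are
  handled downstream through the registered extent, and the registration
  phase picks up a small bias (≲2°) on markedly non-square hulls.
* Intermediate-mixing presets (`strips2`, `strips4`, `checkerboard`) are
  approximate reconstructions of layouts published only as figures; their
  reference SI values at the 100-µm span are ≈0.89, 0.83 and 0.52. The two
  strip layouts bracket the published intermediate values; a droplet-scale
  checkerboard is already nearly fully mixed at that span.
* SI is 2D only (square neighbourhoods); no 3D segregation index is
  provided.
* The 3D separator uses a single scale σ and a single eigenvalue test — no
  multi-scale search or vesselness-style composite, and whether the
  original λ₁ threshold was global or per-stack adaptive is unknowable from
  the description; the default here is per-stack (90th percentile), with an
  absolute override.
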