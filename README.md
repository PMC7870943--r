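# printarray

Quantification of droplet-printed microbial community arrays in R.

Micron-scale droplet printing arranges two bacterial genotypes in designed
patterns: ~110-µm agarose droplets, each carrying ~70 founder cells, fuse
into a 7×8 array in which each cell grows into a clonal microcolony
(~15 µm). How strongly the genotypes are spatially mixed is summarised by a
segregation index, and the outcome of their competition by frequency and
productivity. This package implements the full measurement pipeline for
such experiments, for microbial ecologists and image analysts who need the
numbers rather than the printer:

* **2D segmentation** — average-intensity z-projection, Gaussian smoothing,
  Otsu foreground, dark-ridge subtraction and prominence-seeded watershed;
  per-colony position, orientation, length/width, area and channel
  brightness from image moments.
* **3D segmentation** — rough intensity threshold refined by
  Hessian-eigenvalue detection of dark separating features: with eigenvalues
  ordered |λ₁| ≥ |λ₂| ≥ |λ₃|, voxels whose signed λ₁ exceeds a threshold
  mark the dark ridges between packed colonies and are carved out of the
  rough mask before 26-connectivity labelling.
* **Print geometry** — centre and side length
  L = 6·r̄ / (√2 + ln(1+√2)); radial debris isolation; registration to the
  x–y axes from the phase of the k = 4 DFT of the convex hull's radial
  profile, θ = ¼(π − arg Σₙ d(φₙ)e^(−i8πn/N)); Delaunay neighbour–neighbour
  distances over interior colonies.
* **Segregation index** — per-pixel genotypes by dual Otsu thresholding;
  sᵢ(h) = kin fraction over the (2h+1)² square neighbourhood; SI(h) = mean
  over all genotype-bearing pixels, from 0.5 (mixed at scale h) to 1.0
  (segregated); profiles over spans and comparison against the printing
  map's idealised reference image.
* **Outcome metrics** — frequency f = A_a/(A_a+A_b) and productivity
  p = A_a/A_S on area/volume/cell/CFU bases, flow-cytometry core gating
  (2^9.5 fluorescence split, first 3000 gated events) and growth-curve
  doubling times (OD 0.2–0.7 window).
* **Synthetic scenes** — a seeded generator that emulates the printed
  arrays (printing maps, reference masks, noisy micrographs and stacks with
  ground truth), so the whole pipeline is testable without imaging data.

## Worked example

Simulate a fully segregated 7×8 print, run the pipeline, and compare the
measured segregation profile with the printing map's theoretical reference:

```r
library(printarray)

res <- run_pipeline(list(seed = 4,
                         map = list(pattern = "segregated_halves")))
round(res$si$reference$comparison[, c("span_px", "span_um", "si_measured",
                                      "si_reference", "delta")], 3)
#>   span_px span_um si_measured si_reference delta
#> 1       5   7.575       0.999        0.999 0.001
#> 2      10  15.150       0.997        0.997 0.001
#> 3      20  30.300       0.991        0.991 0.001
#> 4      50  75.750       0.964        0.963 0.001
#> 5      66  99.990       0.947        0.944 0.003
#> 6     100 151.500       0.921        0.916 0.005
round(res$metrics$frequency, 3)
#>     A     B
#> 0.495 0.505
```

The measured print reproduces the reference SI at every span (a fully
segregated array reads ≈0.94 at the 100-µm span, h = 66 px), and the two
genotypes — which differ only in label — end at equal area frequencies.
The run also reports the print geometry: side length ≈ 857 µm for the
designed 770 × 880 µm array, registration angle ≈ 0° for an unrotated
print.

The numbered scripts under `analysis/` walk the same pipeline across the
whole mixing ladder (segregated, two strip layouts, checkerboard, fully
mixed — reference SI 0.94, 0.89, 0.83, 0.52, 0.50 at the 100-µm span),
writing scenes, colony tables, geometry summaries, SI profiles and outcome
metrics under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment.R
Rscript analysis/03_geometry.R
Rscript analysis/04_segregation.R
Rscript analysis/05_metrics.R
```

## Documentation

The methods vignette (`vignettes/printarray-methods.Rmd`) describes the
models and their assumptions, the parameters that matter and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and known limitations.
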