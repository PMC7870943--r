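Package: printarray
Title: Quantification of Droplet-Printed Microbial Community Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis and quantification pipeline for micron-scale
    droplet-printed bacterial communities. Segments fluorescent microcolonies
    in 2D micrographs (ridge detection, morphological watershed and intensity
    thresholding) and 3D confocal stacks (Hessian-eigenvalue separation of
    closely packed colonies), isolates and registers printed arrays via a
    k = 4 Fourier shape descriptor, computes Delaunay neighbour-neighbour
    distances, the segregation index SI(h) over square neighbourhoods, and the
    ecological outcome metrics frequency and productivity on area, volume,
    cell-count or CFU bases. Includes a seeded synthetic-scene generator that
    emulates printed arrays (printing maps, idealised reference masks, noisy
    micrographs and stacks with ground truth) so the full pipeline is testable
    without imaging data, plus flow-cytometry gating and growth-curve doubling
    time helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deldir,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
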