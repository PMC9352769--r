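Package: ParticleScan
Title: Tile-Scan Particle Segmentation and Surface Contamination Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement chain for particulate surface contamination assessed by
    tile-scanning brightfield microscopy of exposed coupon windows. Provides a
    synthetic tile-scan generator with ground truth (Poisson-placed particles
    with bimodal size structure, shape families, flow-axis density gradients,
    and shadow-casting macroscopic objects), a two-zoom two-pass segmentation
    (constant low-zoom threshold, stack-statistic high-zoom threshold,
    shadow-frame rejection, crop-centered local refinement), particle
    morphometry with size-class assignment, and campaign statistics:
    per-window densities, size distributions, flow-axis stratification
    profiles with an asymmetry index, accumulation kinetics, and contamination
    rate versus occupancy rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, Rcpp, tiff, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
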