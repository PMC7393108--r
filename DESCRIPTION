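Package: treemorph
Title: Tree Morphometrics and Allometry from Terrestrial Laser Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts stem and crown morphological traits from segmented
    single-tree point clouds (tree height, breast-height diameter by Taubin
    circle fitting, crown base from convex-hull area profiles, maximum
    canopy cross-section, gap-fraction leaf area index with Lang-Xiang
    clumping correction, trunk dominance ratio, branch-order ratios), fits
    nonlinear power-law quantile envelopes to height-canopy-diameter data
    by exact pinball-loss minimization, compares them with the allometric
    module of LPJ-family dynamic global vegetation models, and runs the
    associated trait-trait and trait-environment statistics (Pearson and
    partial correlation, standardized PCA, centroid-linkage clustering).
    Includes a synthetic-forest generator with analytic ground truth so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
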