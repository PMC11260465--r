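Package: nanofoci
Title: Nanoscale Topology and High-Content Quantification of DNA Repair Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for DNA double-strand-break repair
    foci: simulation of STED nanoscopy scenes, high-content microscopy fields
    and traffic-light-reporter flow events with known ground truth;
    prominence-based spot detection with sub-pixel 2D Gaussian localization;
    reconstruction of repair-focus topology (nanodomain counts and radial
    distances around a BRCA1-marked center); per-nucleus cell-cycle gating
    from DAPI and EdU intensities with ploidy-normalized foci counts;
    homologous-recombination versus mutagenic end-joining reporter gating;
    and the accompanying statistical procedures (Mann-Whitney U, unpaired
    t-test, two-way ANOVA, Fisher's exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    tiff,
    jsonlite,
    EBImage,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
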