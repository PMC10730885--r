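Package: choriflow
Title: Choriocapillaris Flow-Deficit Quantification from En-Face OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow deficits on en-face optical
    coherence tomography angiography (OCTA) slabs: Phansalkar local adaptive
    binarization, choriocapillaris flow area (CCFA) ratio, spatial
    heterogeneity as the coefficient of variation of the CCFA ratio over an
    18x18 tile grid, superficial vessel length density by skeletonization,
    axial-length (Littmann-Bennett) magnification correction, and a
    two-threshold impaired-flow classifier.  Includes a synthetic OCTA image
    and cohort generator with exported ground truth (lobular choriocapillaris
    texture, controllable flow-void density and heterogeneity, branching
    vessel networks of known centerline length), self-calibration of the
    generator against target flow statistics, and the downstream statistical
    pipeline (Kruskal-Wallis, Mann-Whitney, Pearson correlation, ROC with
    Youden cutoffs, 2x2 odds ratios, age-adjusted logistic regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
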