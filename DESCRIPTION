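Package: SwarmThresh
Title: Multilevel Otsu Thresholding with a Hybrid Sand-Cat/Whale Swarm Optimizer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilevel image thresholding by maximization of the Otsu
    between-class variance criterion, driven by an adaptive two-phase
    hybrid metaheuristic that runs sand cat swarm optimization (SCSO) for
    an exploration phase and hands its incumbent to the whale optimization
    algorithm (WOA) for an exploitation phase. Includes canonical PSO, GWO,
    WOA and SCSO baselines, an exhaustive brute-force oracle for small
    instances, class-mean image reconstruction, full-reference quality
    metrics (PSNR, SSIM, FSIM), binary overlap metrics (Dice, Jaccard,
    Hausdorff), pixel and neighbor-pixel correlation diagnostics, a seeded
    synthetic fixture generator emulating multi-modal histopathology-like
    intensity histograms, and a benchmarking harness for
    algorithm-by-threshold-level sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Segmentation, Visualization, Classification
RoxygenNote: 7.3.3
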