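Package: dynpet
Title: Kinetic Analysis and Time-Frame Binning Optimization for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compartment-model analysis of dynamic PET time-activity
    curves (TACs) at the volume-of-interest level, built around amino-acid
    tracer (FDOPA) imaging of glioma. Implements frame-schedule parsing and
    binning of continuous curves, bolus-arrival detection, synthetic
    image-derived input functions with metabolite (parent-fraction) and
    hematocrit corrections, forward simulation of the 1T2k+VB, 2T3k+VB and
    2T4k+VB compartment models, bounded Levenberg-Marquardt fitting with
    small-sample Akaike (AICc) model selection, Logan graphical analysis,
    a Poisson-noise Monte Carlo experiment comparing frame-binning schemes
    against a target K1, a seeded synthetic lesion cohort generator with
    paired static uptake (SUV, TBRmax) values, and the paired Wilcoxon /
    Benjamini-Hochberg / Spearman statistical layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
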