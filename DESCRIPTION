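Package: growthswitch
Title: Quantitative Analysis of an Inducible RNA Polymerase Growth Switch
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterization of an Escherichia coli
    strain in which transcription of the rpoBC operon (the beta and beta'
    subunits of RNA polymerase) is placed under IPTG-inducible control,
    turning growth into an externally switchable phenotype. The package
    couples a mechanistic ODE simulator of the switch (dilution-limited RNA
    polymerase, ultrasensitive Hill coupling of growth rate to beta'
    concentration, fluorescent-reporter maturation, glucose-to-glycerol
    bioconversion) with the analysis stages used to characterize such strains:
    exponential growth-rate estimation from microplate absorbance kinetics,
    maturation-corrected reporter quantification, dose-response threshold and
    Hill fitting, smoothing-spline instantaneous product-yield estimation,
    constrained flux-balance analysis of maximal glycerol yield, and
    single-cell lineage elongation analysis with division-arrest detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    jsonlite,
    xml2,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
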