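Package: nmrmetab
Title: 1D NMR Metabolomics Processing and Metabolic Tracer Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing of 1D NMR spectra for metabolomics: Bruker
    experiment import and export, apodization, zero filling, Fourier
    transformation, manual and automatic phase correction (including a
    reference-spectrum, baseline-driven algorithm minimised with Powell's
    conjugate direction method), chemical shift referencing,
    post-acquisition water suppression, spline baseline correction, and a
    complete pre-processing chain (region exclusion, segmental alignment,
    noise filtering, bucketing, total-sum and probabilistic quotient
    normalization, generalized-log variance stabilization) with export to
    MetaboAnalyst CSV and Excel workbooks. Also implements the
    computational core of 13C metabolic tracer analysis: HSQC multiplet
    models driven by carbon-carbon scalar couplings, automatic peak
    picking, line-shape fitting with quality flags, and estimation of
    isotopomer distributions from multiplet fractions combined with GC-MS
    mass-isotopologue distributions by constrained least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    zip,
    optparse
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
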