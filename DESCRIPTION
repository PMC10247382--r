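Package: adnafrac
Title: Stepwise-Fraction Ancient DNA Authentication and Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ancient DNA recovered in stepwise
    extraction fractions from osseous artefacts: family-level taxonomic
    binning of mitochondrial fragments with explicit detection filters,
    authentication via terminal cytosine deamination with exact binomial
    intervals, mitochondrial consensus calling and diagnostic-position
    support, present-day contamination estimation, outgroup-f3 and
    ABBA-BABA D-statistics with block jackknife, X/autosome genetic sex
    inference, PCA projection of low-coverage samples, and strict-clock
    molecular dating by root-to-tip regression. Includes simulators for
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
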