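Package: pugfold
Title: Fold Placement, CD Quantification, and Exchange Kinetics of Poly(UG) RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for long poly(UG) ("pUG") repeat RNAs, which
    fold into left-handed G-quadruplexes of 12 UG repeats. Scans sequences
    for pUG repeat runs, enumerates and simulates placements of
    non-overlapping 12-repeat folds on a repeat chain (including adjacent
    double-fold statistics and predicted RNase T1-resistant fragments),
    converts raw circular dichroism ellipticity to molar CD absorption and
    derives fraction-folded and mean-fold-count statistics, fits
    single-exponential folding traces, mono- and biexponential
    hydrogen/deuterium exchange decays and Boltzmann melting curves, and
    implements a stochastic segmental register-exchange model of partial
    unfolding. A seeded synthetic-data generator emulates every supported
    data type so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    seqinr,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
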