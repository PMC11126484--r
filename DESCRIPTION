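Package: nsip
Title: Quantitative Analysis of 15N-DNA Stable Isotope Probing of Ammonia
    Oxidizers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying isotope incorporation in 15N-DNA stable
    isotope probing (DNA-SIP) experiments on nitrifying soil communities.
    Converts refractive index to CsCl buoyant density, normalizes per-fraction
    qPCR gene-abundance profiles, identifies heavy fractions by comparing
    15N- against 14N-treatment profiles, and estimates 15N-labeled gene
    abundances of ammonia-oxidizing archaea, bacteria and comammox
    Nitrospira. Also computes net nitrification rates, acetylene inhibition
    and log10/ANOVA comparisons from microcosm chemistry, summarizes amplicon
    (Zotu) composition of heavy versus light fractions, and includes a
    synthetic-data generator simulating CsCl gradient banding of isotopically
    labeled DNA and urea-amended microcosm nitrogen dynamics for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
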