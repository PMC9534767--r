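Package: ecdnadyn
Title: Population Dynamics of Randomly Segregating Extrachromosomal DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the copy-number dynamics of extrachromosomal DNA (ecDNA)
    in growing cell populations. ecDNA elements lack centromeres and are
    partitioned binomially between daughter cells at mitosis. The package
    provides single-division segregation models (binomial ecDNA versus
    chromosomal inheritance with rare mis-segregation), an individual-based
    Gillespie simulator of exponentially growing populations under selection,
    numerical integration of the deterministic copy-number density equations
    with their moment closed forms, Kolmogorov-Smirnov and Shapiro-Wilk
    comparison utilities with a subsampling resolution analysis, end-to-end
    selection scenarios (CRISPR-derived ecDNA induction, cell-line expansion,
    drug adaptation with withdrawal), and synthetic-data generators emulating
    daughter-pair FISH counts, interphase FISH tables and droplet digital PCR
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
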