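Package: latcline
Title: Latitudinal Allele-Frequency Clines in Range-Wide SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and analysis of latitudinal allele-frequency clines in
    biallelic SNP panels spanning replicated geographic gradients, as arise in
    range-wide population-genomic surveys of anadromous fish. Provides Genepop
    and genotype-CSV input with standard locus filtering; per-locus binomial
    logistic regression of allele frequencies on latitude with a steep-change
    (fitted range) clinal classifier and threshold-scan diagnostic; a
    permutation plus exact hypergeometric test for cross-lineage overlap of
    clinal architecture; Weir-Cockerham F_ST, observed heterozygosity,
    two-level AMOVA and isolation-by-distance regression; DAPC-style K = 2
    membership coefficients with south-to-north standardization; generalized
    logistic models of clustering coefficients against latitude, distance and
    climate (inflection point, AIC, McFadden pseudo-r2); least-cost marine
    distances over a land-masked grid with non-metric multidimensional
    scaling re-projection; VIF-pruned regression, redundancy analysis and
    partial Mantel environmental association; and a seeded two-lineage
    genotype simulator (Balding-Nichols drift with planted logistic clines)
    so the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vegan,
    igraph,
    geosphere,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
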