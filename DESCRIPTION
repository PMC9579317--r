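Package: immqtl
Title: QTL Mapping and Variance Analysis for Bi-Parental Immortalized
    Heterozygous Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic analysis of bi-parental pure-inbred lines (doubled
    haploids or recombinant inbred lines) together with the immortalized
    heterozygous populations derived from them: backcross-type hybrids to
    either parent (IB1, IB2) and an immortalized F2 (IF2) made by crossing
    pairs of pure lines.  Provides linkage-map handling and drawing,
    one-way ANOVA with broad-sense heritability and a combined
    across-population decomposition into additive and dominance variance
    on the F2 reference scale, interval mapping (IM) and inclusive
    composite interval mapping (ICIM) by EM on normal mixtures for single
    populations and for the five combined designs (IBC, IFL, IBL, IBF,
    BFL), permutation thresholds, meiosis-level population simulation
    under Kosambi, Haldane or Morgan mapping functions, and QTL detection
    power analysis with false discovery rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
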