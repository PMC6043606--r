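Package: clonescan
Title: Detecting Clonal Asexual Lineages in Multi-Isolate Diploid Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing clonal, obligately asexual lineages from
    sexually recombining isolates in whole-genome resequencing of diploid
    microbial eukaryotes mapped to a haploid majority-rules reference.
    Implements the per-position non-reference read fraction (R) statistic and
    genotype-class calling, Hardy-Weinberg equilibrium diagnostics (the 2:1
    heterozygous to homozygous non-reference expectation, the (1/2)^n
    SNP-sharing bound and an exact binomial test on unlinked sites),
    negative-binomial detection of SNP deserts with boundary comparison across
    isolates, cross-isolate SNP-call refinement, genotype-concordance crossover
    density estimation, a maximum-SNP-sharing cladogram with divergence-time
    estimates from private SNP counts, and discrete-generation competition
    simulations of obligate asexuals against facultative sexuals. A synthetic
    data generator produces diploid genotypes and error-bearing pileup count
    tables with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
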