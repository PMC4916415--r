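Package: triotdt
Title: Transmission Disequilibrium Tests under Genotype-Calling Error in
    Parent-Offspring Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how non-symmetric
    genotype-calling errors distort transmission-based rare-variant association
    tests in parent-offspring trios. Provides a Hardy-Weinberg trio cohort
    simulator over rare-variant gene panels, an error injector for the two
    dominant miscall modes (heterozygote called reference homozygote, and the
    reverse) targeted at parents or offspring, Mendelian-consistency screening,
    single-marker and gene-collapsed transmission disequilibrium tests,
    closed-form expectations for how each error scenario shifts aggregate
    transmitted/non-transmitted allele tallies, and type-I-error/power/QQ-band
    evaluation over replicated simulations. Reads and writes VCF, PED and
    gene-map files for use with external callers and pedigree tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
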