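Package: twinEEM
Title: Lineage Tracing of Monozygotic Twinning from Early Embryonic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of early human embryogenesis with post-zygotic
    mutation barcoding, and inference of twin clonal architecture from bulk and
    single-cell sequencing readouts. Early embryonic mutations (EEMs) acquired
    during the first cell divisions mark the two earliest lineages (L1, L2)
    whose descendants compose both co-twins. The package detects anchor and
    counter-anchor EEM clusters in twin-vs-twin VAF space, estimates the
    lineage contributions (a, b) per twin, classifies pairs as para-, sub- or
    full-identical, estimates cord-blood chimerism of monochorionic twins by
    binomial maximum likelihood, reconstructs dropout-aware single-cell
    phylogenies, and provides the contingency and rank statistics used at
    cohort level, together with a seeded synthetic cohort generator with full
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
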