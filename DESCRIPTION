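Package: gbsmap
Title: Genotype QC, Imputation, Linkage Maps and QTL Mapping for GBS-Derived RIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building high-density genetic maps from error-prone,
    sparse genotyping-by-sequencing (GBS) genotypes of biparental recombinant
    inbred line (RIL) populations. Implements anchor-marker linkage grouping
    and misallocation/inversion detection, a Fisher's-exact anchor filter for
    error-prone loci, hidden-Markov-model imputation of parental origin with a
    masking-based accuracy evaluation, SMOOTH-style sliding-window removal of
    spurious double recombinants, riself-corrected Kosambi map construction,
    recombination-bin collapsing, windowed recombination-rate estimation, and
    composite interval mapping by Haley-Knott regression with permutation
    thresholds and Bayes credible intervals. Includes a single-seed-descent
    simulator of F-generation RIL populations with GBS-style artifacts
    (beta-dispersed missingness, genotyping errors, misallocated markers,
    inverted blocks, viability-driven segregation distortion) and a full
    ground-truth ledger, so every pipeline stage can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
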