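Package: greedysnp
Title: Greedy Forward SNP Selection with Regularized Least-Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper-based greedy forward feature selection for case-control
    genome-wide association studies using a regularized least-squares (ridge)
    classifier. Each candidate SNP is scored by leave-one-out cross-validation
    computed in constant time per example from the dual variables, and feature
    additions are handled by rank-one matrix updates, so a full selection pass
    costs time linear in samples, SNPs and selected features. Includes a
    space-efficient variant that trades the cache matrix for per-step singular
    value decompositions, p-value filter and filter-then-wrapper baselines
    built on an exact 3x2 genotype association test, a nested cross-validation
    protocol with permutation control, PLINK binary and TSV genotype input
    with standard quality-control filters, and a case-control genotype
    simulator with planted causal variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
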