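Package: peckscan
Title: Count-Trait GWAS, Selection-Signature Meta-Analysis and Cluster
    Mapping in a Divergent-Line F2 Chicken Cross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for mapping count-valued pecking-behaviour
    traits (feather pecks delivered, aggressive pecks delivered/received)
    in a 960-hen F2 cross between lines divergently selected for feather
    pecking. Implements single-marker Poisson-GLM association with fixed
    hatch, sire and dam effects, a Sidak-type genome-wide correction,
    Storey q-values, Weir-Cockerham F_ST selection-signature p-values
    with permutation, Fisher's combined-probability meta-analysis, a
    distance-chained SNP-cluster construction with weak-SNP bounds,
    EM-based two-locus r2 linkage-disequilibrium decay profiling, and
    Welch-test differential-expression enrichment restricted to
    association clusters. A synthetic-data generator emulates the full
    study design (two divergent founder lines, reciprocal F1 crossing,
    960 F2 hens in four hatches, SNP-chip genotypes, brain expression
    arrays) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
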