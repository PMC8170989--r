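Package: epimutr
Title: Epimutation Discovery and CpG-Island-Methylator-Phenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering epimutations (promoter-hypermethylation
    driven gene silencing) in CpG island methylator phenotype (CIMP) tumors
    from methylation-array beta values. Implements top-variance CpG-island
    probe selection with Ward clustering for CIMP-high/low/non subtyping;
    promoter methylation aggregation and a rank-sum/Benjamini-Hochberg
    engine for differential methylation, expression and protein calling
    with tri-omic intersection; a clone-by-passage consensus caller for
    knockout differential methylation with a random-pairing permutation
    null; signature overlap statistics with bootstrap significance, CpG
    context binomial enrichment, and gene-set hypergeometric overlap; plus
    a synthetic methylation-array simulator with planted truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
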