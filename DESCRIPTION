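Package: rmystr
Title: Mutation Rates and Discriminating Power of Y-STR Panels in
    Paternal Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating Y-chromosomal short tandem repeat (Y-STR)
    mutation rates by direct count in deep-rooted paternal pedigrees, and for
    quantifying the power of standard (Yfiler) and rapidly mutating (RM13,
    RM11) Y-STR panels to discriminate between related and unrelated men.
    Includes a forward simulator of haplotypes under the stepwise mutation
    model with truth logging, maximum-parsimony mutation-event counting on
    pedigree graphs, pooled, per-locus and diachronically binned rate
    estimators with binomial-quantile confidence intervals, iterative Grubbs
    screening of outlier pedigrees, bootstrap summaries of per-couple
    mutation counts, and a discriminant-analysis-of-principal-components
    (DAPC) classifier returning sub-lineage membership probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
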