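Package: megaDE
Title: Cross-Study Mega-Analysis of Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines per-study log2 fold-change effect sizes across
    independent case/control expression studies under fixed-effect and
    DerSimonian-Laird random-effects models, with a heterogeneity-driven
    model switch (Cochran's Q compared against its degrees of freedom).
    Includes study-level covariate regression of effect sizes, Fisher-exact
    gene-set over-representation analysis with Benjamini-Hochberg FDR
    control, assembly of shared-pathway gene-gene interaction networks and
    of signed literature-relation networks linking two diseases through
    intermediate regulators, a synthetic multi-study data generator with
    known ground truth, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
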