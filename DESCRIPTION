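Package: oncoprior
Title: Somatic Variant Prioritisation, Druggability and Co-Expression Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for prioritising somatic variants from annotated tumour
    exomes. Clusters variant-effect prediction rankscores by consensus
    resampling to collapse redundant algorithms, computes a cluster-based
    combination score, applies a germline/COSMIC/DNA-repair filter algebra
    with top-table export, joins prioritised genes to a drug-gene interaction
    snapshot with patient-level druggability summaries, and places variant
    genes in a tumour-specific weighted co-expression network (topological
    overlap, module eigengenes, module membership, gene and module
    significance against clinical traits including survival).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
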