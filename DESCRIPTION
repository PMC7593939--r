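Package: coexshape
Title: Genome-Wide Co-Expression Distribution Shapes for Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns every gene in a normalized expression matrix a
    genome-wide co-expression distribution shape by comparing the histogram
    and moments of its Pearson correlations against eight template
    distributions (unimodal/bimodal x symmetric/skewed x null/non-null)
    through a distance, similarity and probability transformation, then
    prioritizes genes via hypergeometric enrichment of gene categories
    within shapes, chi-square tests on shape dichotomies, condition-split
    shape-shift detection, and PCIT-filtered network connectivity analyses.
    Includes a latent-factor simulator of expression matrices with known
    module structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
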