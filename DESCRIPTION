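Package: dyadprint
Title: Parent-Child Brain Similarity and Dyad Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical framework for quantifying the similarity of brain
    network patterns between parents and their children. Computes Pearson
    similarities between functional-connectivity (FC) and gray-matter-volume
    (GMV) feature vectors of matched parent-child dyads, identifies dyads via
    a pairwise winning-rate accuracy statistic whose chance level is 50%
    irrespective of sample size, and quantifies uncertainty by subsampling
    bootstrap and permutation testing. Includes per-feature contribution
    measures (differential power and group consistency), network-restricted
    and between-network analyses, covariate-split comparisons with paired
    t-tests and Hedges' g, motion scrubbing and confound-residualization
    utilities, and a synthetic dyad-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
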