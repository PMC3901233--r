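Package: metabofp
Title: Metabolite Fingerprinting for Multi-Accession Plant Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for metabolite fingerprinting of multi-accession,
    multi-organ plant metabolomics designs that combine targeted and
    non-targeted mass-spectrometry platforms. Provides replicate quality
    control via Spearman rank correlation, volcano-plot differential
    abundance (Welch t-test on relative abundances), aligned log-ratio
    panels and all-pairs accession fingerprints, a scale-invariant weighted
    Manhattan sample dissimilarity bounded in [0,1], classical
    multidimensional scaling, per-metabolite max-standardization with
    K-means and hierarchical clustering, a log-normal synthetic-data
    generator with planted accession-group and organ effects for recovery
    benchmarking, and a deterministic pipeline driver with a provenance
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
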