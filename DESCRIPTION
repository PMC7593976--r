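Package: rfahkit
Title: Tracing the Origin of Specialized NusG Paralogs in Synthetic Genome Worlds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable comparative-genomics pipeline for tracing how a
    specialized transcription-factor paralog (RfaH-like) arose from a
    ubiquitous housekeeping ancestor (NusG-like). Provides a reproducible
    synthetic genome-world generator with planted duplications, horizontal
    transfers and reduced genomes; affine-gap pairwise protein alignment with
    analytic E-values; center-star multiple alignment and profile models with
    trusted/noise bit-score cutoffs; reciprocal-best-hit orthology; stepwise
    similarity-graph Markov clustering; neighbor-joining trees with
    Robinson-Foulds congruence and longest-path rate comparisons; functional
    site mapping; phyletic profiling with a multi-marker completeness screen
    and conserved-operon context checks; and gene-neighborhood COG category
    enrichment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    mclust,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
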