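Package: tailvirkit
Title: Depth-Stratified Viral Community Analysis for Sulfidic Mine Tailings Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Curation and analysis of viral scaffolds recovered from
    depth-stratified mine-tailings metagenomes. Merges the calls of two
    upstream viral predictors, applies keyword-based hallmark-gene curation
    and prophage boundary trimming, filters candidate scaffolds by an
    unknown-gene fraction rule, clusters curated sequences into
    species-level viral operational taxonomic units (vOTUs) by average
    nucleotide identity and alignment fraction, computes library-size
    normalized coverage and relative abundance, links viruses to host
    genome bins via CRISPR protospacers, prophage containment and shared
    genomic content, calls indicator COGs between surface and deep layer
    groups with an exact rank-sum test and Benjamini-Hochberg correction,
    flags sulfate-assimilation auxiliary metabolic genes (COG0175), and
    provides the permutation-based community-ecology statistics (ANOSIM,
    PERMANOVA, Mantel, PCoA) used to relate viral communities to
    prokaryotic communities and geochemistry. Includes a seeded synthetic
    mine-tailings community generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tools,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
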