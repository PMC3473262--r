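Package: degphylo
Title: Phylogeny-Based Standardized Nomenclature for the Plant Deg/HtrA Protease Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to standardize gene-family nomenclature across plant genomes by
    phylogenetic analysis, developed around the Deg/HtrA family of ATP-independent
    serine endopeptidases. Validates candidate family members (His-Asp-Ser catalytic
    triad, protease/PDZ domain architecture), aligns protease domains with a
    consensus of progressive alignments, infers bootstrapped maximum-likelihood
    phylogenies, extracts supported clades, assigns reference-anchored ortholog
    groups and standardized names, checks domain-arrangement concordance, and
    computes the conserved core set of family members shared by all species.
    Includes a gene-family simulator (duplication/loss birth-death along a species
    tree, sequence divergence, proteolytic inactivation) with known ground truth,
    and bundled inventory tables for five photosynthetic model organisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
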