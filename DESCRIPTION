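Package: cladistinct
Title: Posterior Tree-Sample Summaries, Mk Ancestral States, and Clade
    Trait Distinctness Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for summarizing Bayesian posterior samples of
    phylogenetic trees (clade support with Monte-Carlo error, average
    standard deviation of split frequencies, potential scale reduction
    factors, posterior probabilities of monophyly hypotheses with
    floating taxa), for marginal ancestral-state reconstruction of
    multistate ordered and unordered morphological characters under the
    Mk model with gamma rate variation averaged over a tree sample, and
    for distinctness and uniqueness indices that diagnose clades by
    their reconstructed ancestral traits. Includes NEXUS character
    matrix I/O with polymorphism, GC-composition bias summaries by
    partition and codon position, and seeded generators of synthetic
    trees, character matrices, compositionally biased alignments and
    pseudo-posterior tree samples for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
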