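Package: stemevol
Title: Evolution of RNA Stem-Loop Structures on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of mutational patterns in RNA secondary structure
    evolution. Annotates stems, loops and pseudoknots from consensus
    structural alignments, computes per-sequence realized stem lengths,
    reconstructs ancestral stem lengths (squared-change parsimony),
    stem presence and ancestral sequences (unit-cost Sankoff parsimony)
    on a reference phylogeny, classifies stem gain and loss events into
    whole-stem insertion/deletion versus pairing changes by base
    substitutions and indels, builds gap-aware log-odds substitution
    matrices for single nucleotides and base pairs, and summarises
    stem-length variation by k-means clustering and principal component
    analysis. Includes a simulator of structured RNA evolution along a
    tree (whole-stem indels, compensatory and non-compensatory base-pair
    substitutions, in-stem indels) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
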