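Package: frasschem
Title: Antimicrobial Interaction, Dereplication and Chemotype Analyses for
    Beetle-Gallery Streptomyces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the chemical ecology of wood-degrading
    beetle galleries and their actinomycete communities. Computes fractional
    inhibition from resazurin plate fluorescence and classifies pairwise
    antimicrobial interactions under the Bliss Independence model; annotates
    LC-MS feature tables against a compound library with ppm/retention-time
    tolerances, adduct co-elution checks, replicate-presence rules and
    identification levels 1-3; builds Jaccard/UPGMA chemical-dissimilarity
    dendrograms and scores their agreement with a phylogeny by tanglegram
    entanglement; and analyses colony-count fold changes from substrate
    competition assays. Ships synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
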