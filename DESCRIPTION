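Package: nrpsmith
Title: NRPS Assembly-Line Annotation and Cyclic Lipopeptide Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates multi-modular non-ribosomal peptide synthetase (NRPS)
    proteins into condensation-adenylation-thiolation modules, predicts
    adenylation-domain substrate specificity by Stachelhaus-signature
    nearest-neighbour matching and by phylogenetic placement, types
    condensation (starter / dual condensation-epimerization / conventional)
    and tandem thioesterase domains, applies the co-linearity rule to predict
    cyclic lipodepsipeptide products with residue stereochemistry and
    macrolactonization candidates, and verifies predicted structures by
    molecular-formula algebra, monoisotopic masses and adduct m/z against
    mass-spectrometric evidence. Includes neighbor-joining trees, patristic
    distances with threshold grouping, NMR chemical-shift heuristics for
    depsi-bond location and alkene geometry, and a seeded synthetic-data
    generator providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    phytools,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
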