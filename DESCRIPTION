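Package: groovepred
Title: Knowledge-Based Prediction of DNA-Binding Location and Groove
    Orientation on Protein Structures
Version: 0.1.0
Authors@R:
    person("Rhea", "Calloway", email = "rcalloway@example.org",
           role = c("aut", "cre"))
Description: Builds an amino-acid to nucleotide geometric knowledgebase from
    protein-DNA complex structures and uses it to predict where and in which
    orientation double-stranded DNA binds on a query protein structure.
    Conserved surface residues are clustered into candidate DNA-binding units
    (DBUs), ranked by residue-level DNA-binding propensity, analysed by
    principal component analysis to estimate the tangent direction of the
    bound DNA groove, and combined with residue-frame-local base-atom clouds
    to place and score candidate base locations with core exclusion and
    diversity sampling.  Includes an ideal B-DNA fixture generator with known
    groove ground truth, relative solvent accessibility via an internal
    Shrake-Rupley implementation, fixed-column PDB reading and writing, and
    evaluation utilities (location error, phosphate-derived groove tangents,
    residue-level precision and sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
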