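Package: insertscan
Title: Rigidity-Based Analysis of Exhaustive Double Insertion Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how pairs of amino-acid insertion mutations
    affect protein structure. Enumerates and annotates the exhaustive space of
    double-insertion mutants for a protein, detects stabilizing interactions
    (hydrogen bonds and hydrophobic tethers) from PDB structures, builds a
    body-bar-hinge mechanical model and runs the (6,6) pebble game to obtain
    rigid cluster decompositions, and computes per-mutant stability metrics:
    hydrogen bond count, cluster configuration entropy, and the rigidity
    order parameter. A statistical layer identifies outlier mutants, tallies
    residue, pair and position frequencies, compares alpha-helix insertion
    groups with Cohen's d and two-sample t-tests, and normalizes outlier
    rates by amino-acid size class. A synthetic-data module generates
    ideal-geometry polypeptides, random bar frameworks, and simulated mutant
    metric ensembles with planted effect sizes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
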