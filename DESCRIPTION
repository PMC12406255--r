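Package: ScaffoldMatch
Title: Structural Scaffold Matching and Molecular Grafting for Stabilized Peptides
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-guided engineering of stabilized peptide
    probes. Mines structure libraries for disulfide-rich helix-loop-helix
    scaffolds that conformationally match a bioactive epitope, using
    C-alpha-based secondary-structure assignment, disulfide connectivity
    detection, and framework-constrained rigid-body superposition (Kabsch
    and a combinatorial-extension-style aligner). Splices epitope variants
    into scaffold loops to enumerate grafted chimeras with terminal and
    side-chain modifications, computes monoisotopic and average masses of
    the modified peptides, profiles per-column conservation of aligned
    homolog sets, and fits the accompanying assay statistics (constrained
    three-parameter dose-response EC50, one-phase serum decay, TEER and
    apparent permeability). Includes seeded synthetic generators for every
    fixture class the workflow consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
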