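Package: cleavescan
Title: Conformational-Selection Scoring of Protease Substrate Cleavability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts how accessible a protein's N-terminus is to a
    sequence-specific protease by conformational selection. The pipeline
    generates a diverse conformational ensemble of the flexible N-terminal
    peptide with a stochastic torsional search biased by a local-elevation
    memory potential on the terminal N-C distance, ligates the sampled
    conformers back onto the rigid protein body by backbone superposition,
    relaxes clashes with a bounded steepest-descent minimizer, reduces the
    ensemble with neighbor-count RMSD clustering, grafts each representative
    conformer into a protease active-site template at the scissile bond, and
    scores cleavability as the fraction of conformers whose protease-substrate
    nonbonded interaction energy is favorable. Ships a simplified united-atom
    force field and synthetic structure generators so the whole pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
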