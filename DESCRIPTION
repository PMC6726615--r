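Package: distfold
Title: Protein Model Generation from Predicted Inter-Residue Distance
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts predicted inter-residue distance distributions
    (distograms), backbone hydrogen-bond donor/acceptor maps and torsion
    angle predictions into NOE-like restraints, builds backbone models by
    distance-geometry embedding followed by restrained simulated
    annealing, and refines them over an iterative predict-build-reseed
    loop with ensemble clustering and representative selection.  Includes
    a synthetic prediction oracle so the whole pipeline is testable
    without trained networks, a small softmax network for estimated model
    accuracy (expected TM-score), effective-sequence-count statistics for
    multiple sequence alignments, and TM-score/Kabsch structure
    comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
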