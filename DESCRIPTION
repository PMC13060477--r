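Package: qccc
Title: Cell-Cell Communication Inference by Quantum-Circuit Distribution Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cell-cell communication between two cell populations from
    single-cell expression data measured under non-interacting (mono-culture)
    and interacting (co-culture) conditions. Gene activity is binarized and
    amplitude-encoded into a two-register quantum statevector; an entangling
    circuit of controlled-RX gates is then learned so that the circuit maps
    the non-interacting state distribution onto the interacting one,
    minimizing the sum of per-register Kullback-Leibler divergences. The
    entangling topology is proposed by thresholding the difference of global
    density matrices and selected by greedy local search, multi-epoch
    stochastic construction, or QUBO-based selection; gate angles are then
    refined by continuous optimization. Fitted circuits are dissected by
    sequential gate ablation and transcribed into directed inter- and
    intracellular interaction networks. Includes a rule-based synthetic data
    generator with known ground-truth regulatory structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
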