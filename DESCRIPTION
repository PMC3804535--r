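Package: swaloop
Title: Stepwise Assembly for Protein Loop Structure Prediction
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerative, residue-by-residue ("stepwise assembly") prediction of
    protein loop conformations on a fixed scaffold. Loops are grown as N- and
    C-terminal fragments over a dynamic-programming build-up graph with
    backbone torsion grid sampling, Ramachandran filtering, rotamer-based
    side-chain optimization, energy-ordered leader clustering, cyclic
    coordinate descent chain closure with a linear chainbreak penalty, and
    quasi-Newton torsional minimization under a transparent surrogate
    all-atom energy function. Includes a synthetic-scaffold fixture generator
    with planted-optimum loops for download-free recovery benchmarks, loop
    environment descriptors, native-loop optimization baselines, and
    energy-versus-RMSD reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
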