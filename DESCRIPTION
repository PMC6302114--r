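Package: irmetric
Title: Geometric Evaluation of Neural Input-State Representations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how well a set of neural input states, encoded as a
    non-negative activity matrix, lets a readout neuron with non-negative
    synaptic weights approximate arbitrary desired outputs.  The
    representation error Ir(C) is the mean squared distance from points of
    the unit output hypercube to the conical hull of the matrix columns.  It
    is computed analytically, by enumerating the cone's face lattice,
    partitioning the hypercube into polytope regions nearest to each face,
    and integrating the squared residual in closed form over each region;
    and numerically, by midpoint-rule or Monte-Carlo sampling with a
    non-negative least-squares solve per sample point.  Includes spike-train
    binning into state matrices, delimited-text input/output, reference
    example matrices, a seeded random-matrix generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
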