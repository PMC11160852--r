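Package: pfanet
Title: Product Feedback Alignment and Related Credit-Assignment Rules for Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Layer-level implementations of error backpropagation and its
    biologically motivated alternatives for multilayer neural networks:
    feedback alignment (FA), direct feedback alignment (DFA), sign-concordant
    feedback (SF), the Kolen-Pollack rule (KP), and product feedback alignment
    (PFA, and its semi-orthogonal variant PFA-o), in which the backward pathway
    is factored through an expanded intermediate neuron population as a product
    of a plastic matrix R and a fixed random matrix B. Includes dense and
    convolutional forward/backward/update kernels, alignment-angle and
    norm-ratio diagnostics, Marchenko-Pastur analysis of the feedback product
    B'B, sparse feedback masking, synthetic teacher-network task generators,
    an MNIST IDX reader, and a small training harness with tidy result tables
    and ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
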