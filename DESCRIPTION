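Package: rpo
Title: Red Piranha Optimization and Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Swarm-intelligence optimizer modelling the cooperative hunting of
    red piranha: a searching (exploration) phase led by randomly drawn scouts,
    a logarithmic-spiral encircling phase around a virtual prey placed at the
    mean of the k best agents, and a greedy attacking phase with optional
    collision detection at checkpoint iterations. Includes the binary variant
    (sigmoid transfer of continuous position updates to bit vectors) for
    wrapper feature selection with a Gaussian Naive Bayes fitness, a
    synthetic clinical-table generator emulating a heavily missing,
    imbalanced diagnostic dataset, packaged worked-example fixtures with a
    replay harness, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
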