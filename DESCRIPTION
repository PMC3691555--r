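Package: hippomem
Title: Simulation of Hippocampal Episodic Memory Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A quantitative rate-model simulator of the hippocampal episodic
    memory system: dentate-gyrus competitive pattern separation of entorhinal
    grid-cell input, sparse mossy-fiber randomization of CA3 representations,
    a diluted CA3 autoassociative attractor storing discrete, continuous and
    mixed object-place memories with analytic and empirical storage-capacity
    analysis, perforant-path cued recall, a CA1 heteroassociative readout,
    and an adaptation-based temporal-order sequence memory. Includes seeded
    synthetic-pattern generators, an end-to-end one-trial object-place recall
    task, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, tools, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
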