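Package: seqcollab
Title: Generative Simulation of Sequential Collaboration and the Wisdom of Crowds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of sequential collaboration: chains of
    contributors who each see the latest numerical judgment for an item and
    decide to adjust or maintain it, based on an internal distribution of
    plausible values governed by person-level expertise and change tendency
    and item-level difficulty. Implements the normal, skew-normal, and
    biased-normal plausible-value families (including the skew-normal
    distribution function via Owen's T), the independent-judgment
    unweighted-averaging baseline (wisdom of crowds), chain and crowd
    simulation engines with reproducible seeded substreams, dependent-variable
    summaries (change probability, change magnitude, accuracy, improvement),
    expertise proxies and chain-composition analyses, named presets encoding
    published simulation designs, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
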