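Package: retellchain
Title: Transmission-Chain Analysis of Serially Retold Stories
Version: 0.1.0
Authors@R: person("Retellchain", "Developers", role = c("aut", "cre"),
    email = "retellchain@example.org")
Description: Tools for analysing serial-reproduction (transmission chain)
    experiments in which a story is retold several times by humans or by a
    large language model. Provides readers and validators for chain corpora
    and affect ratings; rule-based tokenization, part-of-speech
    categorization and negation detection; concept extraction against a
    WordNet-style sense inventory with gloss-overlap disambiguation and
    per-transition survival, novelty and density metrics; merging of
    psycholinguistic norms (age of acquisition, concreteness, valence,
    arousal, frequency) with word-preservation logistic models;
    negative-binomial and beta-binomial trend regressions with
    producer-specific dispersion; a Bayesian linear-spine plus compression
    model of rating stability with region-of-practical-equivalence
    decisions; and a seeded synthetic chain-and-ratings generator with
    recorded ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
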