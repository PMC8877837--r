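Package: frsys
Title: Hybrid Fuzzy-Rough Inference for Posture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A hybrid fuzzy-rough inference system for lying-pose detection
    from depth-camera silhouette features. Provides scalar fuzzy connectives
    (negations, implications, t-norms and t-conorms, means, OWA, and
    directionally monotone pre-aggregations), a precedence indicator built
    from an aggregation and a negation, knowledge measures dual to fuzzy
    entropy, a Mamdani inference engine in classic and knowledge-augmented
    modes with centre-of-gravity defuzzification, LEM2 rough-set rule
    induction over discretised decision tables, and a synthetic feature
    generator with confusion-matrix evaluation for end-to-end experiments.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
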