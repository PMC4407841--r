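Package: nof1bayes
Title: Bayesian Combined N-of-1 Trials for Rare-Disease Treatment Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design, simulation and analysis machinery for series of
    double-blind placebo-controlled N-of-1 (single-patient multi-crossover)
    trials combined through a hierarchical Bayesian random-effects model,
    as used to evaluate mexiletine in non-dystrophic myotonia. Provides
    treatment-set schedule generation with block randomization, a synthetic
    diary-data generator (random intercept, random treatment slope,
    within-person residual noise), a conjugate Gibbs sampler for population
    and per-patient treatment effects with shrinkage, per-patient sequential
    interim stopping rules on posterior probabilities, simulation-based
    assurance (expected posterior probability) sample-size calculation,
    histogram-based expert prior elicitation with linear opinion pooling,
    trial-level cost-effectiveness analysis (ICER with nonparametric
    bootstrap intervals), and deterministic scoring rules for quantitative
    myotonia instruments (needle-EMG discharge grading, grip relaxation
    time, transient-paresis force decline).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
RoxygenNote: 7.3.3
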