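Package: coilcea
Title: Cost-Effectiveness of Recanalization-Reducing Adjuncts to
    Intracranial Aneurysm Coiling
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probabilistic Markov cohort model comparing standard coil
    embolization of unruptured intracranial aneurysms with standard coiling
    plus an adjunct health technology that reduces the aneurysm
    recanalization rate. Provides the full decision-analytic pipeline:
    distribution construction from published moments, a vectorized 60-cycle
    state-transition engine with discounted cost and QALY accrual,
    probabilistic sensitivity analysis with replication-based credible
    intervals, cost-effectiveness acceptability curves, expected value of
    (partial) perfect information, a price-versus-efficacy threshold
    analysis, tornado and scenario analyses, and an independent
    individual-level microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
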