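Package: pstlearn
Title: Probabilistic Selection Task Simulation, Q-Learning Agents and
    Behavioural Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the Probabilistic Selection Task (PST) in its
    modified (two-pair) and original (three-pair, threshold-gated)
    variants, generates complete trial schedules, and runs Q-learning
    agents with softmax choice, separate learning rates for positive and
    negative prediction errors, optional medication-state-dependent
    parameters and an overnight value-retention stage.  Provides
    maximum-likelihood model fitting with AIC/BIC comparison and
    parameter-recovery harnesses, the full behavioural metric set
    (optimal-choice accuracy, choose-A/avoid-B, win-stay/lose-shift,
    memory-difference scores, chance-level filtering) and the matching
    inferential battery (paired and independent t-tests, exact Wilcoxon
    signed-rank, 2x2 repeated-measures ANOVA, partial eta squared,
    Cohen's d variants, Bonferroni control).  A synthetic-cohort
    generator reproduces the within-subject 2x2 medication-condition
    design with configurable effect injections so the whole analysis
    pipeline runs without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
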