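Package: aflearn
Title: Two-Stage Learned Decision Support for Atrial Fibrillation Rhythm
    Management
Version: 0.1.0
Authors@R:
    person("aflearn", "maintainers", email = "aflearn@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage machine-learning policy for choosing
    among four atrial fibrillation rhythm-management strategies (rate
    control, external cardioversion, antiarrhythmic medication, ablation).
    Stage one mimics expert clinicians with a linear-score classifier
    trained by stochastic gradient descent; stage two is linear Q-learning
    in a contextual-bandit framing, trained from follow-up outcome rewards
    (-2*stroke - hospitalization - symptomatic recurrence) in batches of 8
    patients.  Includes a blended recommender, a synthetic patient-world
    simulator with known ground-truth expert and outcome models, policy
    value and regret evaluation against brute-force optima, and a
    command-line pipeline with reproducible, seeded, JSON/CSV artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
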