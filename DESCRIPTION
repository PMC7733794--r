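Package: dualnav
Title: Dual-System Reinforcement Learning for Spatial and Nonspatial Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an agent that combines a hippocampal learner based on the
    successor representation over allocentric place-cell features with a
    dorsolateral-striatal model-free Q-learner over egocentric landmark-cell
    features, arbitrated by the reliability of each system's prediction errors.
    Provides grid-world arenas (linear track, water maze, plus maze, open field)
    and two-step decision-task graphs, boundary-vector-cell and landmark-cell
    feature models, the arbitration dynamics, and the simulated experimental
    protocols and analyses (adapted water-maze navigation, place versus response
    strategy on the plus maze with outcome devaluation, landmark versus boundary
    blocking, two-step stay-probability analysis, and the correlation between
    model-based planning and allocentric place memory).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
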