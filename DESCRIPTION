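Package: splitsteal
Title: Emotion Prediction by Inverse Planning in the Split-or-Steal Game
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A generative intuitive-theory-of-emotion toolkit for the public
    one-shot prisoner's dilemma ("Split or Steal"). Infers a player's
    preferences (money, advantageous and disadvantageous inequity aversion,
    and second-order reputation concerns) and belief about the opponent from
    a single cooperate/defect choice by exact Bayesian inversion of a softmax
    utility-maximisation model on a discrete grid; computes appraisal
    variables (achieved utility, prediction error, own- and opponent-action
    counterfactuals, opponent surprise) from the inferred mind and the game
    outcome; and learns sparse emotion-concept transformations that map
    appraisal distributions to quantitative predictions of 20 emotions via a
    Gaussian-mixture likelihood with a Laplace prior on the weights. Includes
    lesioned model variants, concordance-based evaluation with bootstrap
    confidence intervals, personalization-bias analysis, and a synthetic
    observer-data generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
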