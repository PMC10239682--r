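---
title: "Emotion prediction by inverse planning: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion prediction by inverse planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitsteal)
```

## The model

`splitsteal` models how an observer predicts the emotional reaction of a
player in the public one-shot prisoner's dilemma known from the
"Split or Steal" gameshow. Two players face a pot; each secretly chooses
to cooperate (Split, `C`) or defect (Steal, `D`). Both cooperating
splits the pot, both defecting destroys it, and a lone defector takes
everything. The observer sees a single condition tuple (a1, a2, pot)
and produces quantitative intensity predictions for 20 emotions.

The package decomposes this judgement into three modules.

**Inverse planning.** A simulated player's latent mind comprises six
preference weights in [0, 1] — how much the player values money,
avoiding *advantageous* inequity (AIA: winning more than the opponent)
and avoiding *disadvantageous* inequity (DIA: being left behind), each
both first-order ("base") and second-order ("reputation": caring what
others will believe they value) — together with a belief `pi_a2` that
the opponent will cooperate and a pre-game reference point `pi_money`
for expected winnings. The expected base utility of an action is the
belief-weighted Fehr–Schmidt sum

    E[U_base(a1)] = sum_{a2} P(a2) [ w_money nu(money - pi_money)
                                     - w_aia nu(AI) - w_dia nu(DI) ],

where `nu(x) = sign(x) log(1 + |x|)` is a sign-adjusted logarithm
capturing diminishing marginal utility symmetrically for gains and
losses. Reputation utilities add what a naive observer would infer
about the player's base preferences after seeing each action,
`E[w_base | a1]`, valued as `nu(E[w|a1] * pot)` with a negative sign on
money (players want to be seen as non-greedy) and positive signs on the
inequity aversions. Choice follows a softmax policy with inverse
temperature `lambda`; Bayesian inversion of this policy on a discrete
grid prior turns one observed action into an exact joint posterior over
all seven mind dimensions.

**Computed appraisals.** Given an inferred mind and the realized
outcome, the package computes a 19-component appraisal vector: for each
base feature the achieved utility (AU), the prediction error
(PE = achieved minus expected), the own-action counterfactual (CFa1:
utility contrast to the unchosen action, weighted by the probability
the player would have chosen it under the updated belief) and the
opponent-action counterfactual (CFa2: contrast weighted by the prior
belief the opponent would choose otherwise); for each reputation
feature AU and CFa1 only (reputation utilities are deterministic given
the player's own action, so their PE and CFa2 are identically zero,
which is what makes the inventory total 19); plus the opponent
surprise `|1[a2 = C] - pi_a2|`.

**Emotion concepts.** A learned transformation maps appraisal samples
to emotion means through a logistic link,
`mu = logit^-1(k psi beta + b)` with steepness `k = 0.4`, and scores
empirical emotion vectors under a uniformly weighted Gaussian mixture
over the posterior appraisal samples of the row's condition with a
shared diagonal covariance. The MAP objective adds an independent
Laplace(0, tau) prior on every beta weight, scaled by the number of
observations so the data/prior balance is invariant to dataset size.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1.0 | softmax inverse temperature, on the scale of `nu`-utilities; 0 = random choice |
| `k` | 0.4 | logistic steepness of the concept transform |
| `pi_money` marginal | {0, median pot, max pot}, equal weights | discrete reference-point distribution, integrated out wherever `pi_money` enters |
| grid resolutions | 5 per weight, 6 for `pi_a2` | inference is exact enumeration on this grid; the belief grid matches the empirical 6-point confidence scale |
| pot grid | 8 log-spaced in [$2, $207,365] | the empirical stimulus range; 24 for the full stimulus grid |
| `tau` | CV-selected | Laplace scale; larger = weaker penalty |
| mixture components | full grid, or capped by weighted subsample | appraisal samples per condition in the Gaussian mixture |

`lambda` is a single global constant rather than a fitted parameter:
the empirical treatment is not printed in the source material, and a
fixed value keeps the inversion a pure function of the prior. The
reputation loop inverts the *anonymous* model at depth 1 — the naive
observer does not itself reason about reputation — which terminates
the embedded recursion by construction.

## The synthetic world

No deposited data are required. `synth_world()` fixes a complete
generative state: a generic prior with discretised Beta(2, 2) marginals
on every dimension (most simulated players care moderately about each
feature; extremes are rare), a sparse true transformation (30% of beta
weights nonzero, magnitudes uniform on [0.5, 2] with random sign,
matching the qualitative sparsity of the learned concept maps), and
observer noise of SD 0.1 — the rating-noise scale adopted for emotion
reports as well, chosen so that recovery is feasible at the empirical
study size (~550 observers). The generic training design emulates the
empirical one: each observer completes eight trials, two per outcome
class, pots drawn from the design grid.

Specific players are produced by exponentially *tilting* the generic
prior: log-weights receive `support %*% gamma` with
`gamma ~ N(0, perturb_scale^2)` per dimension. Unstructured
independent noise on the grid weights would average out under
marginalisation and produce no systematic player differences; tilting
shifts marginal means smoothly, the way a personalising description
("software engineer", "city councilman") plausibly would.

What the generator does *not* emulate: real observers' shared rating
idiosyncrasies (halo effects, scale anchoring), disagreement between
observer subpopulations, and any dependence of ratings on photographs
or text. A green recovery test therefore establishes that the
estimation machinery inverts the model's own generative process at
realistic sizes — not that the model fits human data.

## Numerical choices

* **Inversion** is exhaustive enumeration on the grid — exact, no
  sampling error; posteriors are normalised likelihood-times-prior.
* **Optimisation** is accelerated proximal gradient ascent (FISTA with
  adaptive restart) on (beta, b, log sigma^2); the l1 term is handled
  by soft-thresholding, so inactive weights are exact zeros. Stopping:
  relative objective change below 1e-6 (1e-7 in the acceptance runs),
  capped iterations, with a warning (not an error) on non-convergence.
  Variances are parameterised as logs with a floor at 1e-6; intercepts
  are unpenalised.
* **Initialisation**: beta ~ N(0, 0.1^2), intercepts at the logit of
  per-emotion grand means, variances at the empirical per-emotion
  variances. Restarts vary only the seed.
* **tau grid** {30, 100, 300, 1000}: log-spaced around the scale where
  the per-weight penalty `M/tau` is comparable to the data gradient at
  typical fits (M = 4000 observations). Grid search picks, per
  cross-validation fold, the smallest tau (sparsest model) whose mean
  per-player concordance is within one standard error of the best.
* **Zero-variance appraisal components** (e.g. the reputation CFa1
  columns under the inverse-planning lesion, where the lesioned
  reputation table has no action contrast) keep scale 1 and are
  flagged with a warning; the penalty then drives their weights to 0.
* **Degenerate inputs**: an all-zero likelihood (posterior or naive
  observer) raises an error rather than renormalising silently;
  constant inputs to the concordance return 0 with a warning.

## A known identifiability limit

With a binary opponent action, the prediction error decomposes as
`pe_f = pi(not a2) * (U_f(a1, a2) - U_f(a1, not a2))`, which is exactly
`-cf_a2_f`. The two definitions — both stated in the source material —
therefore produce componentwise collinear columns, and after unit-SD
standardisation the 19-column basis is rank-deficient by three (plus
two further near-degenerate directions arising from the correlation
between reputation AU and CFa1). Only the difference
`beta_pe - beta_cf_a2` is identified; the l1 prior selects one point
of a continuum of MAP solutions, typically splitting the identified
coefficient across the pair.

Consequences, verified empirically in the acceptance suite: held-out
predictive concordance is unaffected (predictions depend only on the
identified combination) and sign recovery of large true weights stays
above its 80% criterion (0.85 measured), but true-zero weights whose
collinear partner is active acquire stable, restart-invariant nonzero
estimates (false-positive saturation 0.44 measured). The acceptance criterion
bounding false-positive saturation at 10% is therefore not attainable
under these definitions at any penalty strength that preserves sign
recovery; the test asserts the stated bound and is expected to fail,
documenting the defect rather than masking it.

## Worked example

```{r example, eval = FALSE}
cfg <- planning_config()
prior <- uniform_prior()              # weakly informative default
post_c <- invert(prior, "C", 100000, cfg)
post_d <- invert(prior, "D", 100000, cfg)
round(posterior_expectations(post_c), 3)
round(posterior_expectations(post_d), 3)
# cooperators are inferred to care less about money, more about not
# exploiting the opponent, and to expect cooperation in return

s <- appraisal_distribution(post_c, game_outcome("C", "D", 100000), cfg)
round(appraisal_expectation(s), 2)    # 19 named appraisal components
```

## Limitations

* The grid prior assumes independent marginals unless a joint table is
  supplied; empirical joint structure in attributions is not captured.
* Appraisal definitions reconstruct the printed description; the
  original supplementary formalisation was not available, and the
  component-level details (e.g. any further belief-weighting of the
  opponent surprise) may differ.
* Prospective emotions (hope, fear) and non-binary negotiation
  behaviour ("cheap talk") are out of scope.
* The bootstrap resamples observers (cluster bootstrap) by default;
  the empirical resampling unit of the source analyses is not printed.
* The variance-scaled Pearson correlation is implemented as
  `r * min(1, sd(model) / sd(empirical))` behind a named function so
  it can be corrected if the original definition becomes available.
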