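# splitsteal

Emotion prediction by Bayesian inverse planning in the "Split or
Steal" game.

## What this is

When observers watch a player cooperate or defect in a public one-shot
prisoner's dilemma, they form rich, systematic predictions of how that
player will feel when the outcome is revealed — more *envy* for an
exploited cooperator, more *guilt* for a lone defector, even though
both outcomes may leave the player with the same money. `splitsteal`
implements a complete generative intuitive-theory-of-emotion pipeline
for this setting, for computational cognitive scientists who want to
fit, lesion, and stress-test such models without collecting data:

1. **Inverse planning.** A player's latent mind is a vector of six
   preference weights ω ∈ [0,1] — Fehr–Schmidt monetary and inequity
   concerns (`money`, `AIA`, `DIA`), each at a first-order ("base")
   and second-order ("reputation") level — plus a belief π(a2) that
   the opponent cooperates and a reference point π(money). Expected
   utility of an action is

       E[U(a1)] = Σ_a2 π(a2) [ ω_money ν(money − π_money)
                               − ω_AIA ν(AI) − ω_DIA ν(DI) ]
                  − ω_money^repu ν(E[ω_money|a1]·pot)
                  + ω_AIA^repu ν(E[ω_AIA|a1]·pot)
                  + ω_DIA^repu ν(E[ω_DIA|a1]·pot)

   with ν(x) = sign(x)·log(1+|x|) and choice P(a1) ∝ exp(λ E[U(a1)]).
   `invert()` computes the exact grid posterior P(ω, π | a1).
2. **Computed appraisals.** For an inferred mind and a realized
   outcome: achieved utilities, prediction errors, own- and
   opponent-action counterfactuals, and opponent surprise — a
   19-component vector per posterior sample.
3. **Emotion concepts.** A sparse 19 × 20 weight matrix β maps
   appraisals to 20 emotion intensities through a logistic link
   (steepness k = 0.4), fit by MAP under a per-weight Laplace(0, τ)
   prior against a Gaussian-mixture likelihood over the appraisal
   posterior; τ is chosen by grid search with K-fold cross-validation
   over specific players.

Lesioned variants (`lesion_inverse_planning()`, the
`social_lesion_basis()` fit), Lin's concordance + bootstrap CIs, a
personalization-bias (Δe) analysis, and a full synthetic-observer
generator (`synth_world()`, `generate_emotion_dataset()`,
`generate_specific_players()`) round out the toolkit.

## Worked example

```r
library(splitsteal)
cfg   <- planning_config()          # lambda = 1, public model
prior <- uniform_prior()            # 5-point weight grid, 6-point belief
round(posterior_expectations(invert(prior, "C", 100000, cfg)), 3)
#> w_money_base   w_aia_base   w_dia_base w_money_repu   w_aia_repu
#>        0.492        0.643        0.364        0.501        0.517
#>   w_dia_repu        pi_a2
#>        0.484        0.690
round(posterior_expectations(invert(prior, "D", 100000, cfg)), 3)
#> w_money_base   w_aia_base   w_dia_base w_money_repu   w_aia_repu
#>        0.508        0.363        0.631        0.499        0.484
#>   w_dia_repu        pi_a2
#>        0.515        0.317
```

(Values from a 3 × 4-point grid; the defaults are finer.) A player who
*cooperates* is inferred to care less about money (0.49 < 0.51), more
about not exploiting the opponent (AIA 0.64 > 0.36), less about being
exploited (DIA 0.36 < 0.63), and to expect cooperation in return
(π(a2): 0.69 vs 0.32) — the qualitative inference pattern the package's
acceptance tests assert. Appraisals for the outcome where this
cooperator is betrayed:

```r
s <- appraisal_distribution(invert(prior, "C", 100000, cfg),
                            game_outcome("C", "D", 100000), cfg)
round(appraisal_expectation(s)[c("au_dia_base", "pe_money_base",
                                 "cf_a2_dia_base", "abs_pe_pi_a2")], 2)
#>    au_dia_base  pe_money_base cf_a2_dia_base   abs_pe_pi_a2
#>          -4.19          -3.24           3.51           0.69
```

Negative achieved disadvantageous-inequity utility and monetary
prediction error, a large positive opponent counterfactual ("had they
cooperated I'd be fine") and high surprise: the appraisal signature an
emotion concept turns into *envy* and *contempt*.

## Command line

```sh
Rscript inst/cli/splitsteal-cli.R --stage simulate --config cfg.json --out out/
Rscript inst/cli/splitsteal-cli.R --stage fit --seed 1 --out out/
```

Stages: `simulate` (choice-probability tables), `synth` (synthetic
datasets), `fit` (the full synthetic fit/predict/evaluate pipeline).

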