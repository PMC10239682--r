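test_that("appraisal vectors have the canonical 19 components", {
  cfg <- planning_config()
  minds <- random_minds(30, seed = 31)
  for (oc in outcome_set(12345)) {
    psi <- compute_appraisals(minds, oc, toy_repu(), cfg)
    expect_identical(colnames(psi), appraisal_components())
    expect_identical(dim(psi), c(30L, 19L))
    expect_true(all(is.finite(psi)))
    expect_true(all(psi[, "abs_pe_pi_a2"] >= 0 & psi[, "abs_pe_pi_a2"] <= 1))
  }
})

test_that("achieved utilities match hand evaluation", {
  cfg <- planning_config()
  # all weights zero: every AU component zero
  psi0 <- compute_appraisals(player_mind(),
                             game_outcome("C", "D", 1e5), toy_repu(), cfg)
  au_cols <- grep("^au_", appraisal_components(), value = TRUE)
  expect_true(all(psi0[, au_cols] == 0))
  # CC: no inequity for any mind
  psi_cc <- compute_appraisals(random_minds(10, seed = 32),
                               game_outcome("C", "C", 1e5), toy_repu(), cfg)
  expect_true(all(psi_cc[, c("au_aia_base", "au_dia_base")] == 0))
  # exploited cooperator with unit DIA weight
  m <- player_mind(w_dia_base = 1, pi_money = 0)
  psi <- compute_appraisals(m, game_outcome("C", "D", 1e5), toy_repu(), cfg)
  expect_equal(unname(psi[1, "au_dia_base"]), -nu(1e5))
  # reputation AU: signs per the public-game utility
  m2 <- player_mind(w_money_repu = 1, w_aia_repu = 1, w_dia_repu = 1)
  psi2 <- compute_appraisals(m2, game_outcome("C", "C", 1e4), toy_repu(), cfg)
  expect_equal(unname(psi2[1, "au_money_repu"]), -nu(0.3 * 1e4))
  expect_equal(unname(psi2[1, "au_aia_repu"]), nu(0.7 * 1e4))
  expect_equal(unname(psi2[1, "au_dia_repu"]), nu(0.2 * 1e4))
})

test_that("prediction errors satisfy the AU - EU identity", {
  cfg <- planning_config()
  minds <- random_minds(25, seed = 33)
  pm <- default_pm(cfg)
  for (oc in list(game_outcome("C", "C", 5e4), game_outcome("D", "C", 777))) {
    psi <- compute_appraisals(minds, oc, toy_repu(), cfg)
    # summed PE equals total achieved base utility minus Eq-3.1 value
    eu <- vapply(seq_len(nrow(minds)), function(i)
      oracle_eu_base(minds[i, ], oc$a1, oc$pot, pm$vals, pm$probs),
      numeric(1))
    au_tot <- rowSums(psi[, c("au_money_base", "au_aia_base",
                              "au_dia_base")])
    pe_tot <- rowSums(psi[, c("pe_money_base", "pe_aia_base",
                              "pe_dia_base")])
    expect_equal(pe_tot, au_tot - eu, tolerance = 1e-12)
  }
  # belief point mass on the realized action: no surprise, no PE
  m <- player_mind(w_money_base = 0.8, w_dia_base = 0.4, pi_a2 = 1,
                   pi_money = 0)
  psi <- compute_appraisals(m, game_outcome("C", "C", 1e5), toy_repu(), cfg)
  pe_cols <- grep("^pe_", colnames(psi), value = TRUE)
  expect_true(all(abs(psi[, pe_cols]) < 1e-12))
  expect_equal(unname(psi[1, "abs_pe_pi_a2"]), 0)
  # two-term expectation by hand
  m2 <- player_mind(w_money_base = 1, pi_a2 = 0.5, pi_money = 0)
  psi2 <- compute_appraisals(m2, game_outcome("C", "C", 1e5), toy_repu(), cfg)
  expect_equal(unname(psi2[1, "pe_money_base"]), nu(5e4) - 0.5 * nu(5e4))
})

test_that("opponent surprise is |1[a2 = C] - pi_a2|", {
  cfg <- planning_config()
  cases <- list(list(p = 1, a2 = "C", want = 0),
                list(p = 1, a2 = "D", want = 1),
                list(p = 0.3, a2 = "C", want = 0.7))
  for (cs in cases) {
    m <- player_mind(pi_a2 = cs$p)
    psi <- compute_appraisals(m, game_outcome("C", cs$a2, 10),
                              toy_repu(), cfg)
    expect_equal(unname(psi[1, "abs_pe_pi_a2"]), cs$want)
  }
})

test_that("opponent counterfactuals are belief-weighted contrasts", {
  cfg <- planning_config()
  # pi(not a2) = 0: all CFa2 components vanish
  m <- player_mind(w_money_base = 1, w_aia_base = 1, w_dia_base = 1,
                   pi_a2 = 1, pi_money = 0)
  psi <- compute_appraisals(m, game_outcome("C", "C", 1e5), toy_repu(), cfg)
  cf2 <- grep("^cf_a2_", colnames(psi), value = TRUE)
  expect_true(all(psi[, cf2] == 0))
  # features whose payoff is unchanged by swapping a2 contrast to zero:
  # under a1 = C the AI feature is zero for both a2
  m2 <- random_minds(5, seed = 34)
  psi2 <- compute_appraisals(m2, game_outcome("C", "D", 1e5),
                             toy_repu(), cfg)
  expect_true(all(psi2[, "cf_a2_aia_base"] == 0))
  # hand contrast for money under CD
  m3 <- player_mind(w_money_base = 1, pi_a2 = 0.5, pi_money = 0)
  psi3 <- compute_appraisals(m3, game_outcome("C", "D", 1e5),
                             toy_repu(), cfg)
  expect_equal(unname(psi3[1, "cf_a2_money_base"]),
               (nu(5e4) - nu(0)) * 0.5)
})

test_that("own-action counterfactuals use the updated-belief policy", {
  # indifferent mind: counterfactual weight is exactly 1/2
  cfg <- planning_config(lambda = 3)
  m <- player_mind()  # all weights zero: equal utilities
  oc <- game_outcome("C", "D", 1e4)
  # weight recoverable from a unit money contrast: with w_money_base = 1,
  # pi_money = 0, swapping a1 under a2 = D moves money 0 -> 0 (CD vs DD),
  # so use a2 = C where C->D moves pot/2 -> pot
  oc2 <- game_outcome("C", "C", 1e4)
  m2 <- player_mind(w_money_base = 1, pi_a2 = 0.5, pi_money = 0)
  psi <- compute_appraisals(m2, oc2, toy_repu(), cfg)
  # hand computation: updated belief pins a2 = C; policy from utilities
  # U(C) = nu(pot/2), U(D) = nu(pot) plus repu terms (zero repu weights)
  pD <- 1 / (1 + exp(-3 * (nu(1e4) - nu(5e3))))
  expect_equal(unname(psi[1, "cf_a1_money_base"]),
               (nu(1e4) - nu(5e3)) * pD, tolerance = 1e-12)
  # softmax limit: dominant action drives the weight to zero
  cfg_big <- planning_config(lambda = 1e4)
  m3 <- player_mind(w_money_base = 1, pi_a2 = 0.5, pi_money = 0)
  psi3 <- compute_appraisals(m3, game_outcome("D", "C", 1e5),
                             toy_repu(), cfg_big)
  expect_lt(abs(psi3[1, "cf_a1_money_base"]), 1e-8)
  # indifferent mind gets weight 1/2 (verified through repu contrast)
  m4 <- player_mind(w_money_repu = 1)
  psi4 <- compute_appraisals(m4, game_outcome("C", "C", 1e4),
                             toy_repu(), planning_config(lambda = 0))
  contrast <- -nu(0.8 * 1e4) + nu(0.3 * 1e4)
  expect_equal(unname(psi4[1, "cf_a1_money_repu"]), contrast * 0.5)
})

test_that("reputation utilities depend only on the player's own action", {
  cfg <- planning_config()
  minds <- random_minds(20, seed = 35)
  au_repu <- paste0("au_", c("money", "aia", "dia"), "_repu")
  cf_repu <- paste0("cf_a1_", c("money", "aia", "dia"), "_repu")
  for (a1 in c("C", "D")) {
    pc <- compute_appraisals(minds, game_outcome(a1, "C", 4e4),
                             toy_repu(), cfg)
    pd <- compute_appraisals(minds, game_outcome(a1, "D", 4e4),
                             toy_repu(), cfg)
    # achieved reputation utilities are a2-invariant
    expect_identical(pc[, au_repu], pd[, au_repu])
    # the CFa1 repu *contrast* is a2-invariant: only the counterfactual
    # weight P(not a1 | omega, a2) differs between realized a2 values
    na1 <- other_action(a1)
    w_c <- splitsteal:::policy_given_a2(minds, "C", 4e4, cfg,
                                        toy_repu())[, na1]
    w_d <- splitsteal:::policy_given_a2(minds, "D", 4e4, cfg,
                                        toy_repu())[, na1]
    for (col in cf_repu)
      expect_equal(pc[, col] / w_c, pd[, col] / w_d, tolerance = 1e-9)
  }
})

test_that("appraisal distributions carry posterior weights", {
  cfg <- planning_config()
  prior <- uniform_prior(3L, 4L)
  post <- invert(prior, "C", 1e5, cfg)
  s <- appraisal_distribution(post, game_outcome("C", "D", 1e5), cfg)
  expect_identical(s$weights, post$weights)
  expect_identical(dim(s$psi), c(nrow(prior$support), 19L))
  # expectation equals the weighted sum over support
  expect_equal(appraisal_expectation(s),
               colSums(s$psi * s$weights), tolerance = 1e-15)
  # conditioning mismatch is an error
  expect_error(appraisal_distribution(post, game_outcome("D", "C", 1e5),
                                      cfg), "conditioned")
  # point-mass posterior yields a single-row sample
  pm <- mind_prior(prior$support[5, , drop = FALSE], 1)
  s1 <- appraisal_distribution(pm, game_outcome("C", "C", 100), cfg,
                               repu = toy_repu())
  expect_identical(nrow(s1$psi), 1L)
})

test_that("standardisation yields pooled unit SD and is invertible", {
  cfg <- planning_config()
  prior <- uniform_prior(3L, 4L)
  design <- condition_design(pot_grid(3))
  samples <- appraisal_set(prior, design, cfg)
  std <- standardize_appraisals(samples)
  sds <- splitsteal:::pooled_appraisal_sd(std$samples)
  expect_true(all(abs(sds[!std$zero_variance] - 1) < 1e-9))
  # a component with pooled SD 2 is halved
  doubled <- lapply(samples, function(s) { s$psi <- 2 * s$psi; s })
  raw_sd <- splitsteal:::pooled_appraisal_sd(samples)
  std2 <- standardize_appraisals(doubled)
  expect_equal(unname(std2$scale), unname(2 * raw_sd), tolerance = 1e-12)
  # applying a stored record reproduces the same scaling
  std3 <- standardize_appraisals(samples, scale = std$scale)
  expect_equal(std3$samples[[1]]$psi, std$samples[[1]]$psi)
  # already-unit-SD input is unchanged
  std4 <- standardize_appraisals(std$samples)
  expect_equal(std4$samples[[2]]$psi, std$samples[[2]]$psi,
               tolerance = 1e-9)
})

test_that("lesions behave as documented", {
  prior <- uniform_prior(3L, 4L)
  oc <- game_outcome("C", "D", 2e4)
  # lambda = 0: full model and inverse-planning lesion coincide exactly
  cfg0 <- planning_config(lambda = 0)
  full0 <- appraisal_distribution(invert(prior, "C", 2e4, cfg0), oc, cfg0)
  les0 <- lesion_inverse_planning(prior, oc, cfg0)
  expect_equal(full0$psi, les0$psi, tolerance = 1e-12)
  expect_equal(full0$weights, les0$weights, tolerance = 1e-15)
  # lesion weights are the prior's, for either conditioning action
  cfg <- planning_config(lambda = 2)
  les <- lesion_inverse_planning(prior, oc, cfg)
  expect_identical(les$weights, prior$weights)
  # social lesion is a projection of the full appraisals
  full <- appraisal_distribution(invert(prior, "C", 2e4, cfg), oc, cfg)
  sl <- lesion_social(full)
  expect_identical(colnames(sl$psi), social_lesion_basis())
  expect_identical(sl$psi[, "au_money_base"], full$psi[, "au_money_base"])
  expect_identical(sl$psi[, "pe_money_base"], full$psi[, "pe_money_base"])
})

test_that("weighted subsampling preserves the distribution", {
  cfg <- planning_config()
  prior <- uniform_prior(3L, 4L)
  s <- appraisal_distribution(invert(prior, "C", 1e4, cfg),
                              game_outcome("C", "C", 1e4), cfg)
  sub <- subsample_appraisals(s, 200L, seed = 5)
  expect_lte(nrow(sub$psi), 200L)
  expect_equal(sum(sub$weights), 1, tolerance = 1e-12)
  # expectations agree within Monte Carlo error
  expect_lt(max(abs(appraisal_expectation(sub) -
                      appraisal_expectation(s))), 0.6)
  # identical under the same seed; no-op when n exceeds support
  expect_identical(subsample_appraisals(s, 200L, seed = 5)$weights,
                   sub$weights)
  expect_identical(subsample_appraisals(s, 1e9L, seed = 1), s)
})
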