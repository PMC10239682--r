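# Shared fixtures and independent oracles used across test files.

nu <- function(x) sign(x) * log1p(abs(x))

# A small three-point base prior used for brute-force comparisons.
toy_base_prior <- function() {
  sup <- rbind(
    c(0.2, 0.1, 0.8, 0, 0, 0, 0.2),
    c(0.5, 0.5, 0.5, 0, 0, 0, 0.5),
    c(0.9, 0.8, 0.1, 0, 0, 0, 0.9))
  colnames(sup) <- mind_dimensions()
  mind_prior(sup, c(0.25, 0.5, 0.25), variant = "base")
}

# Independent scalar-arithmetic oracle for expected base utility
# (Eq-by-hand; deliberately written without the package's vectorised
# helpers). pm_vals/pm_probs give the reference-point marginal.
oracle_eu_base <- function(mind, a1, pot, pm_vals, pm_probs) {
  pay <- function(a1, a2) {
    if (a1 == "C" && a2 == "C") c(pot / 2, pot / 2)
    else if (a1 == "C" && a2 == "D") c(0, pot)
    else if (a1 == "D" && a2 == "C") c(pot, 0)
    else c(0, 0)
  }
  one <- function(a2) {
    r <- pay(a1, a2)
    money <- sum(pm_probs * nu(r[1] - pm_vals))
    ai <- max(r[1] - r[2], 0); di <- max(r[2] - r[1], 0)
    mind[["w_money_base"]] * money -
      mind[["w_aia_base"]] * nu(ai) - mind[["w_dia_base"]] * nu(di)
  }
  mind[["pi_a2"]] * one("C") + (1 - mind[["pi_a2"]]) * one("D")
}

# Brute-force softmax policy for the anonymous model (scalar loop).
oracle_policy_anon <- function(mind, pot, lambda, pm_vals, pm_probs) {
  z <- lambda * c(C = oracle_eu_base(mind, "C", pot, pm_vals, pm_probs),
                  D = oracle_eu_base(mind, "D", pot, pm_vals, pm_probs))
  e <- exp(z - max(z))
  e / sum(e)
}

# Exhaustive-enumeration Bayes for the anonymous model on a prior grid.
oracle_invert_anon <- function(prior, a1, pot, lambda, pm_vals, pm_probs) {
  lik <- vapply(seq_len(nrow(prior$support)), function(i)
    oracle_policy_anon(prior$support[i, ], pot, lambda, pm_vals,
                       pm_probs)[[a1]], numeric(1))
  w <- prior$weights * lik
  w / sum(w)
}

default_pm <- function(cfg = planning_config())
  list(vals = cfg$pi_money_values, probs = cfg$pi_money_probs)

# Random mind matrix for property tests.
random_minds <- function(n, seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(runif(n * 6), n, 6), runif(n))
  colnames(m) <- mind_dimensions()
  m
}

# A fixed reputation-expectation table for tests that need one.
toy_repu <- function() {
  rbind(C = c(money = 0.3, aia = 0.7, dia = 0.2),
        D = c(money = 0.8, aia = 0.2, dia = 0.6))
}

# Small standardised appraisal world reused by concept-level unit tests.
tiny_world <- function() {
  if (is.null(.tiny_cache$world))
    .tiny_cache$world <- synth_world(seed = 42, n_omega = 2L,
                                     n_belief = 3L, pots = pot_grid(3),
                                     n_components = 40L)
  .tiny_cache$world
}
.tiny_cache <- new.env(parent = emptyenv())
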