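# Forward planning: expected utilities of cooperating vs defecting for a
# mind endowed with preference weights and beliefs, the embedded
# naive-observer reputation expectation, and the softmax action policy.
#
# All planning functions are vectorised over minds: a "mind matrix" has one
# row per mind and the seven columns of mind_dimensions(), plus optionally
# a pi_money column (reference point; if absent or NA the planning config's
# discrete pi_money marginal is integrated out).

#' Construct a player mind
#'
#' The latent mental contents of a simulated player: six preference
#' weights in \[0,1\] (money, advantageous-inequity aversion and
#' disadvantageous-inequity aversion, each with a first-order "base" and a
#' second-order "reputation" weight), the belief `pi_a2` that the opponent
#' cooperates, and an optional pre-game reference point `pi_money` (USD).
#' When `pi_money` is `NA` the planner marginalises over the discrete
#' reference-point distribution in the [planning_config()].
#'
#' @param w_money_base,w_aia_base,w_dia_base base preference weights in \[0,1\].
#' @param w_money_repu,w_aia_repu,w_dia_repu reputation preference weights.
#' @param pi_a2 probability assigned to the opponent cooperating.
#' @param pi_money reference point in USD (`NA` = marginalise).
#' @return a 1-row mind matrix.
#' @export
player_mind <- function(w_money_base = 0, w_aia_base = 0, w_dia_base = 0,
                        w_money_repu = 0, w_aia_repu = 0, w_dia_repu = 0,
                        pi_a2 = 0.5, pi_money = NA_real_) {
  w <- c(w_money_base, w_aia_base, w_dia_base,
         w_money_repu, w_aia_repu, w_dia_repu)
  stop_if(any(w < 0 | w > 1), "preference weights must lie in [0,1]")
  stop_if(pi_a2 < 0 || pi_a2 > 1, "pi_a2 must lie in [0,1]")
  stop_if(!is.na(pi_money) && pi_money < 0, "pi_money must be >= 0")
  m <- matrix(c(w, pi_a2, pi_money), nrow = 1L,
              dimnames = list(NULL, c(mind_dimensions(), "pi_money")))
  m
}

as_mind_matrix <- function(minds) {
  if (is.data.frame(minds)) minds <- as.matrix(minds)
  stopifnot(is.matrix(minds), all(mind_dimensions() %in% colnames(minds)))
  minds
}

#' Planning configuration
#'
#' @param lambda softmax inverse temperature (>= 0). `lambda = 0` yields a
#'   uniform policy; large values approach deterministic maximisation.
#' @param pi_money_values,pi_money_probs discrete marginal over the
#'   reference point pi_money (USD); probabilities must sum to 1.
#' @param model_variant `"anonymous"` (base utilities only) or `"public"`
#'   (base plus reputation utilities).
#' @param value_fn the value transform applied to USD-scale quantities;
#'   defaults to [value_transform()].
#' @return a `planning_config` list.
#' @export
planning_config <- function(lambda = 1.0,
                            pi_money_values = c(0, stats::median(pot_grid()),
                                                max(pot_grid())),
                            pi_money_probs = NULL,
                            model_variant = c("public", "anonymous"),
                            value_fn = value_transform) {
  model_variant <- match.arg(model_variant)
  stop_if(lambda < 0, "lambda must be >= 0")
  if (is.null(pi_money_probs))
    pi_money_probs <- rep(1 / length(pi_money_values), length(pi_money_values))
  stop_if(length(pi_money_values) != length(pi_money_probs),
          "pi_money marginal values/probs length mismatch")
  stop_if(abs(sum(pi_money_probs) - 1) > 1e-9,
          "pi_money marginal weights must sum to 1")
  stop_if(any(pi_money_values < 0), "pi_money values must be >= 0")
  structure(list(lambda = lambda,
                 pi_money_values = as.numeric(pi_money_values),
                 pi_money_probs = as.numeric(pi_money_probs),
                 model_variant = model_variant,
                 value_fn = value_fn),
            class = "planning_config")
}

# Marginalised value of a monetary payoff relative to the reference point.
# Returns one number per mind row: E_piMoney[ nu(money - piMoney) ], or the
# mind's own reference point when it carries a finite pi_money column.
money_value <- function(money, minds, cfg) {
  n <- nrow(minds)
  pm <- if ("pi_money" %in% colnames(minds))
    unname(minds[, "pi_money"]) else rep(NA_real_, n)
  out <- numeric(n)
  idx_own <- is.finite(pm)
  if (any(idx_own)) out[idx_own] <- cfg$value_fn(money - pm[idx_own])
  if (any(!idx_own)) {
    marg <- sum(cfg$pi_money_probs * cfg$value_fn(money - cfg$pi_money_values))
    out[!idx_own] <- marg
  }
  out
}

# Per-feature base utilities (n x 3: money, aia, dia) of the realized
# outcome (a1, a2, pot) for each mind. Negative signs on the inequity
# terms: weights are aversions.
base_feature_utils <- function(minds, a1, a2, pot, cfg) {
  f <- base_features(game_outcome(a1, a2, pot))
  cbind(money = unname(minds[, "w_money_base"]) *
          money_value(f[["money"]], minds, cfg),
        aia = -unname(minds[, "w_aia_base"]) * cfg$value_fn(f[["ai"]]),
        dia = -unname(minds[, "w_dia_base"]) * cfg$value_fn(f[["di"]]))
}

#' Expected base utility of an action
#'
#' The expected subjective utility of choosing `a1`, integrating the
#' opponent's action over the mind's belief `pi_a2` and the reference
#' point over the config's pi_money marginal:
#' `sum_a2 P(a2) * (w_money*nu(money - pi_money) - w_aia*nu(AI) - w_dia*nu(DI))`.
#'
#' @param minds a mind matrix (or [player_mind()]).
#' @param a1 the action under evaluation.
#' @param pot jackpot, USD.
#' @param cfg a [planning_config()].
#' @return numeric vector, one expected utility per mind.
#' @export
expected_base_utility <- function(minds, a1, pot, cfg = planning_config()) {
  minds <- as_mind_matrix(minds)
  as_action(a1)
  p_c <- unname(minds[, "pi_a2"])
  u_c <- rowSums(base_feature_utils(minds, a1, "C", pot, cfg))
  u_d <- rowSums(base_feature_utils(minds, a1, "D", pot, cfg))
  unname(p_c * u_c + (1 - p_c) * u_d)
}

# Per-feature reputation utilities (n x 3) of choosing a1. repu is the
# 2 x 3 naive-observer expectation table (rows "C","D"; cols money, aia,
# dia). Sign is opposite the corresponding base utility: players want to
# be seen as non-greedy (negative on money) and equity-minded (positive
# on the aversions).
repu_feature_utils <- function(minds, a1, pot, repu, cfg) {
  e <- repu[a1, ]
  cbind(money = -unname(minds[, "w_money_repu"]) *
          cfg$value_fn(e[["money"]] * pot),
        aia = unname(minds[, "w_aia_repu"]) * cfg$value_fn(e[["aia"]] * pot),
        dia = unname(minds[, "w_dia_repu"]) * cfg$value_fn(e[["dia"]] * pot))
}

#' Expected public-game utility of an action
#'
#' Base expected utility plus the reputation utilities derived from what a
#' naive observer would infer about the player's base preferences after
#' seeing `a1` (see [reputation_expectation()]).
#'
#' @inheritParams expected_base_utility
#' @param repu 2 x 3 reputation-expectation table from
#'   [reputation_expectation()].
#' @return numeric vector of expected utilities.
#' @export
expected_public_utility <- function(minds, a1, pot, repu,
                                    cfg = planning_config()) {
  minds <- as_mind_matrix(minds)
  expected_base_utility(minds, a1, pot, cfg) +
    rowSums(repu_feature_utils(minds, a1, pot, repu, cfg))
}

#' Naive-observer reputation expectations
#'
#' What a player expects other people to infer about their base
#' preferences if they choose each action: the posterior mean of each base
#' weight after inverting the *anonymous* forward model on the observed
#' action under the base prior. The embedded theory-of-mind loop is
#' depth 1: the naive observer never reasons about reputation itself, so
#' the recursion terminates.
#'
#' @param base_prior a [mind_prior()] over the base dimensions.
#' @param pot jackpot, USD.
#' @param cfg a [planning_config()]; the anonymous variant is forced
#'   internally.
#' @return 2 x 3 matrix, rows `"C","D"`, columns `money, aia, dia`; each
#'   entry `E[w_f_base | a1]` in \[0,1\].
#' @export
reputation_expectation <- function(base_prior, pot, cfg = planning_config()) {
  cfg_anon <- cfg
  cfg_anon$model_variant <- "anonymous"
  pol <- action_policy(base_prior$support, pot, cfg_anon)
  out <- matrix(NA_real_, 2, 3,
                dimnames = list(c("C", "D"), c("money", "aia", "dia")))
  cols <- c("w_money_base", "w_aia_base", "w_dia_base")
  for (a1 in c("C", "D")) {
    lw <- base_prior$weights * pol[, a1]
    tot <- sum(lw)
    stop_if(tot <= 0, "degenerate base prior: zero total likelihood")
    lw <- lw / tot
    out[a1, ] <- colSums(base_prior$support[, cols, drop = FALSE] * lw)
  }
  out
}

#' Softmax action policy
#'
#' `P(a1) proportional to exp(lambda * E[U(a1)])`, computed in the log
#' domain so extreme `lambda` or utilities cannot overflow. For the public
#' variant a reputation-expectation table is required.
#'
#' @inheritParams expected_base_utility
#' @param repu 2 x 3 table from [reputation_expectation()]; required iff
#'   `cfg$model_variant == "public"`.
#' @return n x 2 matrix of probabilities, columns `"C"` and `"D"`, rows
#'   summing to 1.
#' @export
action_policy <- function(minds, pot, cfg = planning_config(), repu = NULL) {
  minds <- as_mind_matrix(minds)
  eu <- function(a1) {
    if (cfg$model_variant == "public") {
      stop_if(is.null(repu), "public model requires a reputation expectation")
      expected_public_utility(minds, a1, pot, repu, cfg)
    } else {
      expected_base_utility(minds, a1, pot, cfg)
    }
  }
  z <- cbind(C = cfg$lambda * eu("C"), D = cfg$lambda * eu("D"))
  m <- pmax(z[, 1], z[, 2])
  ez <- exp(z - m)
  p <- ez / rowSums(ez)
  colnames(p) <- c("C", "D")
  p
}

#' Sample minds from a prior
#'
#' i.i.d. draws from the discrete support of a [mind_prior()],
#' reproducible given a seed.
#'
#' @param prior a [mind_prior()].
#' @param n number of draws.
#' @param seed integer RNG seed.
#' @return mind matrix with `n` rows.
#' @export
sample_player <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "mind_prior"), n >= 1)
  stop_if(nrow(prior$support) == 0L, "empty prior support")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(prior$support), n, replace = TRUE,
                    prob = prior$weights)
  prior$support[idx, , drop = FALSE]
}
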