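# Computed appraisals: how a simulated player evaluates a realized game
# outcome given their preferences and beliefs. For each base feature
# (money, aia, dia) we compute the achieved utility (AU), utility
# prediction error (PE), own-action counterfactual (CFa1) and
# opponent-action counterfactual (CFa2); reputation features carry AU and
# CFa1 only (they are deterministic given the player's own action); the
# final component is the opponent surprise |PE pi_a2|. 19 components in
# the canonical order of appraisal_components().

# P(a1 | omega, a2): the softmax policy re-evaluated with pi_a2 replaced
# by a point mass on the realized opponent action (the player's updated
# belief). Returns the n x 2 policy matrix.
policy_given_a2 <- function(minds, a2, pot, cfg, repu) {
  m2 <- minds
  m2[, "pi_a2"] <- if (a2 == "C") 1 else 0
  action_policy(m2, pot, cfg, repu = repu)
}

#' Compute appraisal vectors for a set of minds at an outcome
#'
#' Vectorised over minds: one 19-component appraisal vector per row.
#'
#' @param minds mind matrix (e.g. a prior/posterior `support`).
#' @param outcome a [game_outcome()].
#' @param repu 2 x 3 reputation-expectation table (see
#'   [reputation_expectation()]); rows "C","D".
#' @param cfg a [planning_config()].
#' @return n x 19 matrix, columns [appraisal_components()].
#' @export
compute_appraisals <- function(minds, outcome, repu,
                               cfg = planning_config()) {
  minds <- as_mind_matrix(minds)
  a1 <- outcome$a1; a2 <- outcome$a2; pot <- outcome$pot
  na1 <- other_action(a1); na2 <- other_action(a2)
  p_c <- minds[, "pi_a2"]

  u_real <- base_feature_utils(minds, a1, a2, pot, cfg)    # achieved
  u_c <- base_feature_utils(minds, a1, "C", pot, cfg)      # had a2 = C
  u_d <- base_feature_utils(minds, a1, "D", pot, cfg)      # had a2 = D
  au_base <- u_real
  eu_base <- p_c * u_c + (1 - p_c) * u_d                   # per feature
  pe_base <- au_base - eu_base

  # Opponent counterfactual: contrast weighted by belief the opponent
  # would have made the other choice.
  p_na2 <- if (a2 == "C") 1 - p_c else p_c
  u_cf2 <- if (na2 == "C") u_c else u_d
  cf_a2_base <- (u_cf2 - u_real) * p_na2

  # Own-action counterfactual: contrast weighted by the probability the
  # player would have chosen otherwise, given the updated belief about
  # the opponent's action.
  pol2 <- policy_given_a2(minds, a2, pot, cfg, repu)
  p_na1 <- pol2[, na1]
  u_alt <- base_feature_utils(minds, na1, a2, pot, cfg)
  cf_a1_base <- (u_alt - u_real) * p_na1

  au_repu <- repu_feature_utils(minds, a1, pot, repu, cfg)
  au_repu_alt <- repu_feature_utils(minds, na1, pot, repu, cfg)
  cf_a1_repu <- (au_repu_alt - au_repu) * p_na1

  abs_pe <- abs(as.numeric(a2 == "C") - p_c)

  psi <- cbind(au_base, pe_base, cf_a1_base, cf_a2_base, au_repu,
               cf_a1_repu, abs_pe)
  colnames(psi) <- appraisal_components()
  psi
}

#' Appraisal distribution for a condition
#'
#' Evaluates [compute_appraisals()] at every support point of a posterior
#' (full model) or prior (inverse-planning lesion) and attaches the
#' corresponding weights.
#'
#' @param post a `mind_posterior` (or a `mind_prior` for lesioned runs,
#'   in which case `repu` must be supplied).
#' @param outcome a [game_outcome()]; for a posterior its `a1` must match
#'   the conditioning action.
#' @param cfg a [planning_config()].
#' @param repu reputation table; defaults to the one stored on the
#'   posterior.
#' @return an `appraisal_sample`: list with `psi` (n x 19), `weights`
#'   (sum to 1), `condition`, and a `scale` record (NULL until
#'   standardised).
#' @export
appraisal_distribution <- function(post, outcome, cfg = planning_config(),
                                   repu = NULL) {
  stopifnot(inherits(post, "mind_prior"))
  if (inherits(post, "mind_posterior")) {
    stop_if(post$conditioning$a1 != outcome$a1,
            "posterior was conditioned on a different action than outcome$a1")
    repu <- repu %||% post$repu
  }
  stop_if(is.null(repu), "a reputation-expectation table is required")
  psi <- compute_appraisals(post$support, outcome, repu, cfg)
  structure(list(psi = psi, weights = post$weights,
                 condition = list(a1 = outcome$a1, a2 = outcome$a2,
                                  pot = outcome$pot),
                 prior_id = post$player_id, scale = NULL),
            class = "appraisal_sample")
}

#' @export
print.appraisal_sample <- function(x, ...) {
  cat(sprintf("<appraisal_sample: %s%s pot=%g, %d support points%s>\n",
              x$condition$a1, x$condition$a2, x$condition$pot,
              nrow(x$psi), if (is.null(x$scale)) "" else ", standardised"))
  invisible(x)
}

#' Expected appraisal vector of a sample
#'
#' @param s an `appraisal_sample`.
#' @return length-19 named vector of weighted component means.
#' @export
appraisal_expectation <- function(s) colSums(s$psi * s$weights)

# Pooled weighted SD per component across a list of appraisal samples;
# each sample contributes with equal total weight.
pooled_appraisal_sd <- function(samples) {
  k <- length(samples)
  psi <- do.call(rbind, lapply(samples, `[[`, "psi"))
  w <- unlist(lapply(samples, function(s) s$weights / k))
  mu <- colSums(psi * w)
  sqrt(pmax(colSums(w * sweep(psi, 2, mu)^2), 0))
}

#' Standardise appraisal samples to pooled unit SD
#'
#' Each component is divided by its pooled (across conditions) weighted
#' standard deviation, so that the Laplace penalty treats all appraisal
#' variables on a common scale. Components are scaled, not centred. A
#' zero-variance component keeps scale 1 and is flagged.
#'
#' @param samples list of `appraisal_sample`s.
#' @param scale optional precomputed scaling record (from a training set)
#'   to apply to held-out samples.
#' @return list with `samples` (scaled), `scale` (named vector of
#'   divisors) and `zero_variance` (logical flags).
#' @export
standardize_appraisals <- function(samples, scale = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  zero <- NULL
  if (is.null(scale)) {
    sds <- pooled_appraisal_sd(samples)
    zero <- sds <= .Machine$double.eps^0.5
    if (any(zero))
      warning("zero-variance appraisal component(s): ",
              paste(appraisal_components()[zero], collapse = ", "))
    scale <- ifelse(zero, 1, sds)
    names(scale) <- appraisal_components()
  } else {
    zero <- rep(FALSE, length(scale))
  }
  scaled <- lapply(samples, function(s) {
    s$psi <- sweep(s$psi, 2, scale, "/")
    s$scale <- scale
    s
  })
  list(samples = scaled, scale = scale, zero_variance = zero)
}

#' Weighted subsample of an appraisal distribution
#'
#' Draws `n` support points with replacement according to their weights,
#' then deduplicates: the returned sample carries the draw frequencies as
#' weights. Used to cap the number of Gaussian-mixture components during
#' concept fitting.
#'
#' @param s an `appraisal_sample`.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return an `appraisal_sample` with at most `n` distinct rows.
#' @export
subsample_appraisals <- function(s, n, seed = NULL) {
  stopifnot(inherits(s, "appraisal_sample"))
  if (nrow(s$psi) <= n) return(s)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(s$psi), n, replace = TRUE, prob = s$weights)
  tab <- table(idx)
  keep <- as.integer(names(tab))
  s$psi <- s$psi[keep, , drop = FALSE]
  s$weights <- as.numeric(tab) / n
  s
}
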