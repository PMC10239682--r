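# Pipeline helpers: build the full set of per-condition appraisal
# distributions for a design (all four outcomes at each pot) under the
# full model or the inverse-planning lesion.

#' Condition design for a pot grid
#'
#' @param pots numeric vector of pot sizes.
#' @return data.frame with `a1, a2, pot` rows for all four outcome
#'   classes at every pot, plus a `key` column.
#' @export
condition_design <- function(pots = pot_grid()) {
  g <- expand.grid(outcome = c("CC", "CD", "DC", "DD"), pot = pots,
                   stringsAsFactors = FALSE)
  out <- data.frame(a1 = substr(g$outcome, 1, 1),
                    a2 = substr(g$outcome, 2, 2),
                    pot = g$pot, stringsAsFactors = FALSE)
  out$key <- condition_key(out$a1, out$a2, out$pot)
  out
}

#' Appraisal distributions for every condition in a design
#'
#' Runs the model once per design condition: one inversion per (a1, pot)
#' (reused across the two a2 values; the posterior depends only on the
#' player's own action), one naive-observer reputation table per pot,
#' and one appraisal evaluation per condition. Under
#' `lesion = "inverse_planning"` the prior replaces the posterior and the
#' reputation table is prior-based.
#'
#' @param prior a [mind_prior()] over the public-model dimensions.
#' @param design data.frame from [condition_design()].
#' @param cfg a [planning_config()] (public variant).
#' @param base_prior naive-observer prior; defaults to the base marginal
#'   of `prior`.
#' @param lesion `"none"` or `"inverse_planning"`.
#' @param n_max cap on mixture components per condition (weighted
#'   subsample; `Inf` keeps the full grid).
#' @param seed RNG seed for subsampling.
#' @return named list of `appraisal_sample`s keyed by condition key.
#' @export
appraisal_set <- function(prior, design, cfg = planning_config(),
                          base_prior = NULL,
                          lesion = c("none", "inverse_planning"),
                          n_max = Inf, seed = 1L) {
  lesion <- match.arg(lesion)
  if (is.null(base_prior)) base_prior <- base_marginal(prior)
  samples <- vector("list", nrow(design))
  names(samples) <- design$key
  for (pot in unique(design$pot)) {
    if (lesion == "none") {
      repu <- reputation_expectation(base_prior, pot, cfg)
      post <- list(C = invert(prior, "C", pot, cfg, repu = repu),
                   D = invert(prior, "D", pot, cfg, repu = repu))
    } else {
      repu <- prior_reputation_expectation(base_prior)
    }
    for (i in which(design$pot == pot)) {
      oc <- game_outcome(design$a1[i], design$a2[i], pot)
      s <- if (lesion == "none") {
        appraisal_distribution(post[[oc$a1]], oc, cfg)
      } else {
        appraisal_distribution(prior, oc, cfg, repu = repu)
      }
      if (is.finite(n_max))
        s <- subsample_appraisals(s, n_max, seed = seed + i)
      samples[[design$key[i]]] <- s
    }
  }
  samples
}
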