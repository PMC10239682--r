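# Lesioned model variants.
#
# InversePlanningLesion: appraisals are computed under the *prior* over
# minds rather than the action-conditioned posterior, and the embedded
# naive-observer loop is likewise prior-based. Appraisal computation
# itself is unchanged and still depends on a1 through the outcome.
#
# SocialLesion: planning and inversion are left intact, but the appraisal
# basis handed to the emotion-concept transformation is restricted to
# monetary achieved utility and monetary prediction error.

#' Social-lesion appraisal basis
#'
#' @return character vector `c("au_money_base", "pe_money_base")`.
#' @export
social_lesion_basis <- function() c("au_money_base", "pe_money_base")

# Prior-based reputation expectation: without inverse planning the naive
# observer learns nothing from the action, so E[w_base | a1] is the prior
# mean for both actions.
prior_reputation_expectation <- function(base_prior) {
  cols <- c("w_money_base", "w_aia_base", "w_dia_base")
  m <- colSums(base_prior$support[, cols, drop = FALSE] *
                 base_prior$weights)
  out <- rbind(C = m, D = m)
  colnames(out) <- c("money", "aia", "dia")
  out
}

#' Inverse-planning-lesioned appraisal distribution
#'
#' The appraisal pipeline with the posterior replaced by the prior:
#' `P(omega, pi_a2 | a1) = P(omega, pi_a2)`, and the embedded
#' reputation inference replaced by the prior mean.
#'
#' @param prior a [mind_prior()].
#' @param outcome a [game_outcome()].
#' @param cfg a [planning_config()].
#' @param base_prior prior for the (lesioned) naive observer; defaults to
#'   the base marginal of `prior`.
#' @return an `appraisal_sample` carrying prior weights.
#' @export
lesion_inverse_planning <- function(prior, outcome,
                                    cfg = planning_config(),
                                    base_prior = NULL) {
  if (is.null(base_prior)) base_prior <- base_marginal(prior)
  repu <- prior_reputation_expectation(base_prior)
  appraisal_distribution(prior, outcome, cfg, repu = repu)
}

#' Social-lesion projection of an appraisal sample
#'
#' Restricts an appraisal sample to the monetary AU/PE columns. The
#' returned sample equals the corresponding two columns of the full
#' sample; it is a convenience for inspecting the lesion, since
#' [fit_concepts()] with `basis = social_lesion_basis()` performs the
#' same projection internally.
#'
#' @param sample an `appraisal_sample`.
#' @return an `appraisal_sample` with a 2-column `psi`.
#' @export
lesion_social <- function(sample) {
  stopifnot(inherits(sample, "appraisal_sample"))
  sample$psi <- sample$psi[, social_lesion_basis(), drop = FALSE]
  if (!is.null(sample$scale))
    sample$scale <- sample$scale[social_lesion_basis()]
  sample
}
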