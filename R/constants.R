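# Canonical labels and orderings used throughout the package.

#' The 20 emotion labels, canonical order
#'
#' Order is fixed: all emotion matrices and datasets use these names as
#' columns in exactly this order.
#'
#' @export
emotion_labels <- function() {
  c("Devastation", "Disappointment", "Contempt", "Disgust", "Envy",
    "Fury", "Annoyance", "Embarrassment", "Regret", "Guilt",
    "Confusion", "Surprise", "Sympathy", "Amusement", "Relief",
    "Respect", "Gratitude", "Pride", "Excitement", "Joy")
}

#' The 19 appraisal component names, canonical order
#'
#' Base features (money, aia, dia) each carry achieved utility (au),
#' prediction error (pe), own-action counterfactual (cf_a1) and
#' opponent-action counterfactual (cf_a2). Reputation features carry only
#' au and cf_a1: reputation utilities are deterministic given the player's
#' own action, so their prediction error and opponent counterfactual are
#' identically zero and excluded. The final component is the absolute
#' prediction error of the opponent's action.
#'
#' @export
appraisal_components <- function() {
  base <- c("money", "aia", "dia")
  c(paste0("au_", base, "_base"),
    paste0("pe_", base, "_base"),
    paste0("cf_a1_", base, "_base"),
    paste0("cf_a2_", base, "_base"),
    paste0("au_", base, "_repu"),
    paste0("cf_a1_", base, "_repu"),
    "abs_pe_pi_a2")
}

#' Names of the six preference-weight dimensions plus belief
#' @export
mind_dimensions <- function() {
  c("w_money_base", "w_aia_base", "w_dia_base",
    "w_money_repu", "w_aia_repu", "w_dia_repu", "pi_a2")
}

# Social-lesion basis: monetary achieved utility and prediction error only.
social_lesion_basis <- function() c("au_money_base", "pe_money_base")
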