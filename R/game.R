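# Game core: actions, outcomes, payoffs, objective base features, and the
# nonlinear value transform shared by every downstream module.

#' Validate an action
#'
#' Actions in the Split-or-Steal game are "C" (cooperate / Split) and
#' "D" (defect / Steal).
#'
#' @param a character scalar, one of `"C"` or `"D"`.
#' @return the validated action.
#' @export
as_action <- function(a) {
  stop_if(!(is.character(a) && length(a) == 1L && a %in% c("C", "D")),
          "action must be \"C\" or \"D\"")
  a
}

#' Negate an action
#'
#' The counterfactual action: C <-> D. An involution.
#'
#' @param a action ("C" or "D"); vectorised.
#' @return the other action(s).
#' @export
other_action <- function(a) {
  stopifnot(all(a %in% c("C", "D")))
  ifelse(a == "C", "D", "C")
}

#' Construct a game outcome
#'
#' One condition of the game is the tuple (a1, a2, pot): player 1's action,
#' player 2's action, and the jackpot in USD.
#'
#' @param a1,a2 actions, `"C"` or `"D"`.
#' @param pot jackpot in USD, strictly positive.
#' @return a `game_outcome` object (named list).
#' @examples
#' game_outcome("C", "D", 100000)
#' @export
game_outcome <- function(a1, a2, pot) {
  as_action(a1); as_action(a2)
  stop_if(!(is.numeric(pot) && length(pot) == 1L && is.finite(pot) && pot > 0),
          "pot must be a single positive finite number")
  structure(list(a1 = a1, a2 = a2, pot = as.numeric(pot)),
            class = "game_outcome")
}

#' @export
format.game_outcome <- function(x, ...) {
  sprintf("<%s%s, pot = $%s>", x$a1, x$a2, format(x$pot, big.mark = ","))
}

#' @export
print.game_outcome <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Payoffs of a game outcome
#'
#' Both cooperate: the pot is split. Both defect: both leave with nothing.
#' One defects: the defector takes the whole pot.
#'
#' @param outcome a [game_outcome()].
#' @return named numeric vector `c(r1 = , r2 = )` in USD.
#' @examples
#' payoffs(game_outcome("C", "C", 100000))  # 50000 each
#' @export
payoffs <- function(outcome) {
  stopifnot(inherits(outcome, "game_outcome"))
  pot <- outcome$pot
  key <- paste0(outcome$a1, outcome$a2)
  switch(key,
         CC = c(r1 = pot / 2, r2 = pot / 2),
         CD = c(r1 = 0, r2 = pot),
         DC = c(r1 = pot, r2 = 0),
         DD = c(r1 = 0, r2 = 0))
}

#' Objective base features of an outcome
#'
#' The Fehr-Schmidt parametrisation: player 1's monetary payoff (money),
#' advantageous inequity `ai = max(r1 - r2, 0)` and disadvantageous
#' inequity `di = max(r2 - r1, 0)`. These are deterministic functions of
#' the outcome tuple; at most one of ai/di is nonzero.
#'
#' @param outcome a [game_outcome()].
#' @return named numeric vector `c(money =, ai =, di =)` in USD.
#' @export
base_features <- function(outcome) {
  r <- payoffs(outcome)
  c(money = unname(r["r1"]),
    ai = max(r[["r1"]] - r[["r2"]], 0),
    di = max(r[["r2"]] - r[["r1"]], 0))
}

#' Sign-adjusted logarithmic value transform
#'
#' Maps a signed USD-scale quantity to dimensionless utility with
#' diminishing marginal value, treating gains and losses symmetrically:
#' `nu(x) = sign(x) * log(1 + |x|)`. Odd, strictly increasing, concave on
#' the gain side, and fixes the origin. The transform is configurable
#' throughout the package (every consumer takes a `value_fn` argument or
#' reads it from a [planning_config()]), so alternatives such as power
#' laws can be swapped in.
#'
#' @param x numeric vector (signed USD-scale quantities).
#' @return numeric vector of utilities.
#' @examples
#' value_transform(99)    # log(100)
#' value_transform(-99)   # -log(100)
#' @export
value_transform <- function(x) {
  stop_if(any(!is.finite(x)), "value_transform requires finite input")
  sign(x) * log1p(abs(x))
}

#' Default pot grid
#'
#' Eight pot sizes log-spaced over the empirical range $2 to $207,365. Use
#' `n = 24` for the full stimulus-scale grid.
#'
#' @param n number of pot sizes.
#' @param range numeric length-2, USD bounds.
#' @return numeric vector of pots.
#' @export
pot_grid <- function(n = 8L, range = c(2, 207365)) {
  stopifnot(n >= 1L, range[1] > 0, range[2] >= range[1])
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' All four outcome classes for a pot
#'
#' @param pot jackpot in USD.
#' @return list of four [game_outcome()]s in CC, CD, DC, DD order.
#' @export
outcome_set <- function(pot) {
  lapply(c("CC", "CD", "DC", "DD"), function(k)
    game_outcome(substr(k, 1, 1), substr(k, 2, 2), pot))
}

# Stable string key for a condition, used to index sample sets.
condition_key <- function(a1, a2, pot) sprintf("%s%s:%.6g", a1, a2, pot)
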