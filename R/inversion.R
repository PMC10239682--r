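# Bayesian inversion: discrete-grid priors over minds, exact enumeration
# posteriors conditional on an observed action, posterior summaries, and
# empirical prior fitting from observer attribution data.

#' Construct a discrete prior over minds
#'
#' A finite weighted support over the seven mind dimensions (six
#' preference weights plus the belief `pi_a2`). Inference in this package
#' is by exhaustive enumeration on this grid, which makes every posterior
#' exact.
#'
#' @param support matrix or data.frame whose columns include
#'   [mind_dimensions()].
#' @param weights probabilities, one per support row, summing to 1
#'   (renormalised if within 1e-9).
#' @param variant `"base"` (anonymous-model prior over the three base
#'   weights and belief), `"generic"`, or `"specific"`.
#' @param player_id optional identifier for specific-player priors.
#' @return a `mind_prior` object.
#' @export
mind_prior <- function(support, weights = NULL,
                       variant = c("generic", "base", "specific"),
                       player_id = NULL) {
  variant <- match.arg(variant)
  support <- as_mind_matrix(support)[, mind_dimensions(), drop = FALSE]
  if (is.null(weights)) weights <- rep(1 / nrow(support), nrow(support))
  stop_if(length(weights) != nrow(support),
          "weights length must match support rows")
  stop_if(any(weights < 0), "prior weights must be non-negative")
  s <- sum(weights)
  stop_if(abs(s - 1) > 1e-6, "prior weights must sum to 1")
  weights <- weights / s
  rng <- range(support)
  stop_if(rng[1] < 0 || rng[2] > 1, "support values must lie in [0,1]")
  structure(list(support = support, weights = as.numeric(weights),
                 variant = variant, player_id = player_id),
            class = "mind_prior")
}

#' @export
print.mind_prior <- function(x, ...) {
  cat(sprintf("<mind_prior: %s, %d support points>\n",
              x$variant, nrow(x$support)))
  invisible(x)
}

#' Build a product-form grid prior from per-dimension marginals
#'
#' @param marginals named list; each element is a list with `values` and
#'   `probs`. Dimensions omitted default to a point mass at 0 (for
#'   reputation weights in a base prior) or a uniform grid.
#' @param variant prior variant tag.
#' @param player_id optional identifier.
#' @return a [mind_prior()] whose joint weights are the outer product of
#'   the marginals (independence assumption).
#' @export
grid_prior <- function(marginals, variant = "generic", player_id = NULL) {
  dims <- mind_dimensions()
  vals <- lapply(dims, function(d) marginals[[d]]$values %||% 0)
  prbs <- lapply(dims, function(d) marginals[[d]]$probs %||% 1)
  grid <- do.call(expand.grid, c(stats::setNames(vals, dims),
                                 KEEP.OUT.ATTRS = FALSE))
  wgrid <- do.call(expand.grid, c(prbs, KEEP.OUT.ATTRS = FALSE))
  w <- Reduce(`*`, wgrid)
  mind_prior(as.matrix(grid), w / sum(w), variant = variant,
             player_id = player_id)
}

#' Uniform (weakly informative) grid prior
#'
#' Preference weights on `n_omega` equispaced points in \[0,1\]; the
#' belief on `n_belief` points matching the empirical 6-point confidence
#' scale mapped to \[0,1\]. For `variant = "base"` the reputation weights
#' are clamped to 0 so the support stays small.
#'
#' @param n_omega grid resolution per preference weight (default 5).
#' @param n_belief grid resolution for `pi_a2` (default 6).
#' @param variant `"generic"` or `"base"`.
#' @return a [mind_prior()].
#' @export
uniform_prior <- function(n_omega = 5L, n_belief = 6L,
                          variant = c("generic", "base")) {
  variant <- match.arg(variant)
  og <- seq(0, 1, length.out = n_omega)
  bg <- seq(0, 1, length.out = n_belief)
  u <- function(v) list(values = v, probs = rep(1 / length(v), length(v)))
  m <- list(w_money_base = u(og), w_aia_base = u(og), w_dia_base = u(og),
            pi_a2 = u(bg))
  if (variant == "generic") {
    m$w_money_repu <- u(og); m$w_aia_repu <- u(og); m$w_dia_repu <- u(og)
  }
  grid_prior(m, variant = variant)
}

# Collapse a joint prior to an independent base-dimension prior (marginal
# histograms over the base weights and belief; reputation weights pinned
# to 0). Exact when the joint is product-form.
base_marginal <- function(prior) {
  dims <- c("w_money_base", "w_aia_base", "w_dia_base", "pi_a2")
  marg <- lapply(dims, function(d) {
    v <- prior$support[, d]
    agg <- rowsum(prior$weights, group = v)
    list(values = as.numeric(rownames(agg)), probs = as.numeric(agg))
  })
  names(marg) <- dims
  grid_prior(marg, variant = "base")
}

#' Invert a forward model on an observed action
#'
#' Exact Bayes on the prior grid: posterior weight of each support point
#' is proportional to its prior weight times the softmax policy
#' probability of the observed action,
#' `P(omega, pi_a2 | a1) prop P(a1 | omega, pi_a2) P(omega, pi_a2)`.
#'
#' @param prior a [mind_prior()].
#' @param a1 observed action.
#' @param pot jackpot, USD.
#' @param cfg [planning_config()]; its `model_variant` selects the
#'   anonymous or public forward model.
#' @param repu optional precomputed reputation table (public model); if
#'   `NULL` it is derived by inverting the anonymous model under
#'   `base_prior`.
#' @param base_prior prior for the embedded naive observer; defaults to
#'   the base marginal of `prior`.
#' @return a `mind_posterior` (inherits `mind_prior`) with a
#'   `conditioning` record.
#' @export
invert <- function(prior, a1, pot, cfg = planning_config(), repu = NULL,
                   base_prior = NULL) {
  stopifnot(inherits(prior, "mind_prior"))
  as_action(a1)
  if (cfg$model_variant == "public" && is.null(repu)) {
    if (is.null(base_prior)) base_prior <- base_marginal(prior)
    repu <- reputation_expectation(base_prior, pot, cfg)
  }
  pol <- action_policy(prior$support, pot, cfg, repu = repu)
  w <- prior$weights * pol[, a1]
  tot <- sum(w)
  stop_if(tot <= 0, "degenerate posterior: all likelihoods are zero")
  post <- mind_prior(prior$support, w / tot, variant = prior$variant,
                     player_id = prior$player_id)
  post$conditioning <- list(a1 = a1, pot = pot,
                            model_variant = cfg$model_variant)
  post$repu <- repu
  class(post) <- c("mind_posterior", class(post))
  post
}

#' Posterior (or prior) expectations per mind dimension
#'
#' @param post a `mind_prior` or `mind_posterior`.
#' @return named numeric vector of weighted means, one per dimension,
#'   each in \[0,1\].
#' @export
posterior_expectations <- function(post) {
  stopifnot(inherits(post, "mind_prior"))
  colSums(post$support * post$weights)
}

#' Fit an empirical grid prior from attribution ratings
#'
#' Observer attribution data give per-dimension ratings: preference
#' weights in \[0,1\] and the belief on a 6-point confidence scale
#' (mapped to \[0,1\] as `(k - 1)/5`). Each dimension's ratings are
#' histogrammed onto the nearest grid value with add-alpha smoothing, and
#' the joint prior is the outer product of the marginals (documented
#' independence assumption; pass a full joint table to [mind_prior()]
#' directly to override). Weight dimensions use a bin-centre grid
#' (`(i - 1/2)/n_omega`) so that every grid value owns an equal-width
#' slice of \[0,1\] and uniform ratings yield a flat marginal; the
#' belief keeps the endpoint grid `(k - 1)/5` of the confidence scale.
#'
#' @param data data.frame with columns `observer_id, player_id, a1, pot,
#'   dimension, rating`; `dimension` in
#'   `money_base, aia_base, dia_base, money_repu, aia_repu, dia_repu, pi_a2`.
#' @param n_omega,n_belief grid resolutions.
#' @param alpha add-alpha smoothing pseudo-count (default 1).
#' @param variant prior variant tag.
#' @param player_id optional: restrict to one player's rows and tag the
#'   prior.
#' @return a [mind_prior()].
#' @export
fit_prior_from_attributions <- function(data, n_omega = 5L, n_belief = 6L,
                                        alpha = 1, variant = "generic",
                                        player_id = NULL) {
  stopifnot(is.data.frame(data),
            all(c("dimension", "rating") %in% names(data)))
  if (!is.null(player_id)) {
    data <- data[data$player_id == player_id, , drop = FALSE]
    variant <- "specific"
  }
  stop_if(nrow(data) == 0L, "empty attribution dataset")
  og <- (seq_len(n_omega) - 0.5) / n_omega
  bg <- seq(0, 1, length.out = n_belief)
  dim_map <- c(money_base = "w_money_base", aia_base = "w_aia_base",
               dia_base = "w_dia_base", money_repu = "w_money_repu",
               aia_repu = "w_aia_repu", dia_repu = "w_dia_repu",
               pi_a2 = "pi_a2")
  unknown <- setdiff(unique(data$dimension), names(dim_map))
  stop_if(length(unknown) > 0,
          paste("unknown attribution dimensions:",
                paste(unknown, collapse = ", ")))
  hist_on <- function(x, grid) {
    idx <- vapply(x, function(v) which.min(abs(grid - v)), integer(1))
    cnt <- tabulate(idx, nbins = length(grid)) + alpha
    list(values = grid, probs = cnt / sum(cnt))
  }
  marg <- list()
  for (d in names(dim_map)) {
    r <- data$rating[data$dimension == d]
    if (length(r) == 0L) next
    if (d == "pi_a2") {
      stop_if(any(r < 1 | r > 6 | r != round(r)),
              "pi_a2 ratings must be integers 1..6")
      marg[[dim_map[[d]]]] <- hist_on((r - 1) / 5, bg)
    } else {
      stop_if(any(r < 0 | r > 1), "weight ratings must lie in [0,1]")
      marg[[dim_map[[d]]]] <- hist_on(r, og)
    }
  }
  stop_if(length(marg) == 0L, "no usable attribution dimensions")
  grid_prior(marg, variant = variant, player_id = player_id)
}

#' Fit one prior per specific player
#'
#' @inheritParams fit_prior_from_attributions
#' @return named list of [mind_prior()]s keyed by `player_id`.
#' @export
fit_specific_priors <- function(data, n_omega = 5L, n_belief = 6L,
                                alpha = 1) {
  ids <- sort(unique(data$player_id))
  priors <- lapply(ids, function(pid)
    fit_prior_from_attributions(data, n_omega, n_belief, alpha,
                                player_id = pid))
  stats::setNames(priors, as.character(ids))
}
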