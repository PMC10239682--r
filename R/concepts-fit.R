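# MAP learning of emotion concepts: proximal-gradient (FISTA) ascent on
# the mixture log-likelihood with an independent Laplace prior on every
# beta weight, tau selection by grid search + K-fold cross-validation
# over specific players, and restart-based confidence intervals.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Optimiser controls for [fit_concepts()]
#'
#' @param max_iter iteration cap.
#' @param tol relative objective-change stopping tolerance.
#' @param step0 initial step size (default: inverse gradient norm).
#' @param min_logs2 floor on the log-variances.
#' @param verbose print progress every 50 iterations.
#' @return list of controls.
#' @export
fit_control <- function(max_iter = 10000L, tol = 1e-6, step0 = NULL,
                        min_logs2 = log(1e-6), verbose = FALSE) {
  list(max_iter = max_iter, tol = tol, step0 = step0,
       min_logs2 = min_logs2, verbose = verbose)
}

# Random-restart initialisation: beta ~ N(0, 0.1^2), intercepts at the
# logit of per-emotion grand means, variances at the empirical
# per-emotion variances.
init_theta <- function(data, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E <- as.matrix(data[, emotion_labels(), drop = FALSE])
  mu0 <- pmin(pmax(colMeans(E), 0.01), 0.99)
  v0 <- pmax(apply(E, 2, stats::var), 1e-4)
  list(beta = matrix(stats::rnorm(p * 20L, 0, 0.1), p, 20L),
       b = logit(mu0), logs2 = log(v0))
}

#' Fit an emotion-concept transformation by MAP
#'
#' Maximises `log P(E | beta, b, sigma2) + M * log P(beta)` where each
#' beta weight has an independent Laplace(0, tau) prior and M is the
#' number of emotion-vector observations (so the data/prior balance is
#' invariant to dataset size). Optimisation is accelerated proximal
#' gradient ascent (FISTA with adaptive restart and backtracking); the
#' l1 term is handled exactly by soft-thresholding, so irrelevant weights
#' are driven to exact zeros.
#'
#' @param data emotion dataset (`a1, a2, pot` + 20 emotion columns).
#' @param samples named list of standardised `appraisal_sample`s keyed by
#'   `condition_key(a1, a2, pot)`; every condition in `data` must be
#'   covered.
#' @param tau Laplace scale (> 0).
#' @param k logistic steepness (default 0.4).
#' @param basis appraisal components to use (the social lesion passes
#'   [social_lesion_basis()]).
#' @param init optional warm-start `concept_transform` or theta list.
#' @param seed RNG seed for the random initialisation.
#' @param control optimiser controls from [fit_control()].
#' @param scale scaling record to store on the transform.
#' @return a [concept_transform()] with attribute `fit`: list with
#'   `converged`, `iterations`, `objective`, `loglik`, and the objective
#'   `trace`. Non-convergence within `max_iter` is flagged, not an error.
#' @export
fit_concepts <- function(data, samples, tau, k = 0.4,
                         basis = appraisal_components(), init = NULL,
                         seed = NULL, control = fit_control(),
                         scale = NULL) {
  stop_if(tau <= 0, "tau must be positive")
  blocks <- prepare_concept_data(data, samples, basis)
  M <- nrow(data)
  pen <- M / tau
  p <- length(basis)

  theta <- if (is.null(init)) {
    init_theta(data, p, seed)
  } else if (inherits(init, "concept_transform")) {
    list(beta = unname(init$beta), b = unname(init$b),
         logs2 = log(unname(init$sigma2)))
  } else init
  stopifnot(nrow(theta$beta) == p)

  obj_of <- function(th, ll) ll - pen * sum(abs(th$beta))
  flat <- function(th) c(th$beta, th$b, th$logs2)

  og <- mixture_obj_grad(theta, blocks, k)
  obj <- obj_of(theta, og$ll)
  # Initial step: inverse of a crude gradient-scale estimate.
  step <- control$step0 %||%
    (1 / max(1, sqrt(sum(og$gbeta^2) + sum(og$gb^2) + sum(og$glogs2^2))))

  x <- theta; x_prev <- theta
  t_mom <- 1
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    mom <- (t_mom - 1) / t_new
    y <- list(beta = x$beta + mom * (x$beta - x_prev$beta),
              b = x$b + mom * (x$b - x_prev$b),
              logs2 = x$logs2 + mom * (x$logs2 - x_prev$logs2))
    ogy <- mixture_obj_grad(y, blocks, k)
    repeat {
      cand <- list(beta = soft_threshold(y$beta + step * ogy$gbeta,
                                         step * pen),
                   b = y$b + step * ogy$gb,
                   logs2 = pmax(y$logs2 + step * ogy$glogs2,
                                control$min_logs2))
      ll_cand <- mixture_obj_grad(cand, blocks, k, grad = FALSE)$ll
      d <- flat(cand) - flat(y)
      ub <- ogy$ll + sum(c(ogy$gbeta, ogy$gb, ogy$glogs2) * d) -
        sum(d^2) / (2 * step)
      if (is.finite(ll_cand) && ll_cand >= ub - 1e-10 * abs(ub)) break
      step <- step / 2
      stop_if(step < 1e-18, "line search failed: step underflow")
    }
    obj_cand <- obj_of(cand, ll_cand)
    if (obj_cand < obj) {
      # adaptive restart: drop momentum, take a plain proximal step from x
      t_new <- 1
      ogx <- mixture_obj_grad(x, blocks, k)
      cand <- list(beta = soft_threshold(x$beta + step * ogx$gbeta,
                                         step * pen),
                   b = x$b + step * ogx$gb,
                   logs2 = pmax(x$logs2 + step * ogx$glogs2,
                                control$min_logs2))
      ll_cand <- mixture_obj_grad(cand, blocks, k, grad = FALSE)$ll
      obj_cand <- obj_of(cand, ll_cand)
      if (obj_cand < obj) { step <- step / 2; next }
    }
    x_prev <- x; x <- cand
    t_mom <- t_new
    step <- step * 1.05
    trace <- c(trace, obj_cand)
    if (abs(obj_cand - obj) <= control$tol * (abs(obj) + 1)) {
      obj <- obj_cand
      converged <- TRUE
      break
    }
    obj <- obj_cand
    if (control$verbose && it %% 50L == 0L)
      message(sprintf("iter %d  obj %.4f  step %.2e", it, obj, step))
  }
  if (!converged)
    warning(sprintf("fit_concepts: not converged in %d iterations", it))
  out <- concept_transform(x$beta, x$b, exp(x$logs2), k = k, tau = tau,
                           basis = basis, scale = scale)
  attr(out, "fit") <- list(converged = converged, iterations = it,
                           objective = obj,
                           loglik = obj + pen * sum(abs(x$beta)),
                           trace = trace)
  out
}

#' Predicted per-condition emotion expectations
#'
#' @param transform a [concept_transform()].
#' @param samples named list of standardised `appraisal_sample`s.
#' @return matrix, one row per condition (rownames = keys), 20 columns.
#' @export
predict_condition_expectations <- function(transform, samples) {
  out <- t(vapply(samples,
                  function(s) predict_emotions(transform, s)$expectation,
                  numeric(20)))
  colnames(out) <- emotion_labels()
  out
}

#' Empirical per-condition mean emotion vectors
#'
#' @param data emotion dataset.
#' @return matrix keyed like [predict_condition_expectations()].
#' @export
empirical_condition_means <- function(data) {
  keys <- condition_key(data$a1, data$a2, data$pot)
  E <- as.matrix(data[, emotion_labels(), drop = FALSE])
  out <- rowsum(E, keys) / as.numeric(table(keys)[sort(unique(keys))])
  out[sort(unique(keys)), , drop = FALSE]
}

# Concordance between a transform's predictions and a player's empirical
# means over that player's conditions.
player_score <- function(transform, player_samples, player_data) {
  pred <- predict_condition_expectations(transform, player_samples)
  emp <- empirical_condition_means(player_data)
  common <- intersect(rownames(pred), rownames(emp))
  lin_ccc(as.numeric(pred[common, ]), as.numeric(emp[common, ]))
}

#' Select the Laplace scale by grid search + K-fold cross-validation
#'
#' For every tau on the grid, fit the transformation to the generic
#' training data. Specific players are partitioned into folds; within
#' each fold iteration the remaining players form the selection set, the
#' tau that generalises best to them (mean per-player concordance) is
#' chosen, and the held-out players receive predictions from the
#' generic-data fit at that tau. Ties break towards the smallest tau
#' (sparsest model) whose score is within one standard error of the
#' best.
#'
#' @param generic_data,generic_samples GenericPlayers emotion dataset and
#'   its standardised appraisal samples.
#' @param specific_data SpecificPlayers emotion dataset (needs a
#'   `player_id` column).
#' @param specific_samples named list (by player id) of named sample
#'   lists (by condition key), standardised with the training record.
#' @param tau_grid candidate Laplace scales.
#' @param fold_size players held out per fold (default 5).
#' @param seed RNG seed (fold shuffling and fit initialisation).
#' @param control optimiser controls.
#' @param basis appraisal basis.
#' @return list: `fits` (per tau), `tau_grid`, `scores` (player x tau
#'   matrix), `folds` (per fold: players + selected tau), `selected_tau`
#'   (per-fold vector), and `predictions` (per player: predicted and
#'   empirical per-condition matrices plus the tau used).
#' @export
select_tau_cv <- function(generic_data, generic_samples, specific_data,
                          specific_samples, tau_grid, fold_size = 5L,
                          seed = 1L, control = fit_control(),
                          basis = appraisal_components()) {
  stopifnot(length(tau_grid) >= 1L, "player_id" %in% names(specific_data))
  tau_grid <- sort(unique(tau_grid))
  players <- names(specific_samples)

  # Fit once per tau on the generic data, warm-starting from the weaker
  # penalty (largest tau first).
  fits <- vector("list", length(tau_grid))
  names(fits) <- as.character(tau_grid)
  prev <- NULL
  for (tau in rev(tau_grid)) {
    f <- fit_concepts(generic_data, generic_samples, tau, basis = basis,
                      init = prev, seed = seed, control = control)
    fits[[as.character(tau)]] <- f
    prev <- f
  }

  by_player <- split(specific_data, specific_data$player_id)
  scores <- matrix(NA_real_, length(players), length(tau_grid),
                   dimnames = list(players, as.character(tau_grid)))
  for (p in players)
    for (tau in as.character(tau_grid))
      scores[p, tau] <- player_score(fits[[tau]], specific_samples[[p]],
                                     by_player[[p]])

  set.seed(seed)
  shuffled <- sample(players)
  fold_idx <- split(shuffled, ceiling(seq_along(shuffled) / fold_size))
  if (length(players) %% fold_size != 0L)
    warning("player count not divisible by fold size; last fold is smaller")

  folds <- list()
  predictions <- list()
  selected <- numeric(0)
  for (f in seq_along(fold_idx)) {
    held <- fold_idx[[f]]
    sel <- setdiff(players, held)
    m <- colMeans(scores[sel, , drop = FALSE])
    se <- apply(scores[sel, , drop = FALSE], 2, stats::sd) /
      sqrt(length(sel))
    best <- which.max(m)
    ok <- which(m >= m[best] - se[best])
    tau_f <- tau_grid[min(ok)]
    folds[[f]] <- list(players = held, tau = tau_f)
    selected <- c(selected, tau_f)
    ft <- fits[[as.character(tau_f)]]
    for (p in held) {
      predictions[[p]] <- list(
        predicted = predict_condition_expectations(ft,
                                                   specific_samples[[p]]),
        empirical = empirical_condition_means(by_player[[p]]),
        tau = tau_f)
    }
  }
  list(fits = fits, tau_grid = tau_grid, scores = scores, folds = folds,
       selected_tau = selected, predictions = predictions)
}

#' Restart-based confidence intervals for beta weights
#'
#' Repeats the MAP fit from random initialisations and summarises each
#' weight's distribution across restarts: expectation, 95% and 99%
#' quantile intervals, and a saturation flag (99% interval excludes
#' zero).
#'
#' @inheritParams fit_concepts
#' @param n_restarts number of random restarts (default 50).
#' @param seed master seed; per-restart seeds are derived from it.
#' @return a `fit_report`: list with `beta_mean`, `ci95_lo/hi`,
#'   `ci99_lo/hi`, `saturated` (all p x 20 matrices), `objectives`,
#'   `n_restarts`, and `fits` (the individual transforms).
#' @export
beta_confidence <- function(data, samples, tau, n_restarts = 50L,
                            seed = 1L, k = 0.4,
                            basis = appraisal_components(),
                            control = fit_control()) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_restarts)
  fits <- lapply(seeds, function(s)
    fit_concepts(data, samples, tau, k = k, basis = basis, seed = s,
                 control = control))
  p <- length(basis)
  arr <- vapply(fits, function(f) unname(f$beta), matrix(0, p, 20L))
  q <- function(prob) apply(arr, c(1, 2), stats::quantile, probs = prob,
                            names = FALSE)
  ci95 <- list(lo = q(0.025), hi = q(0.975))
  ci99 <- list(lo = q(0.005), hi = q(0.995))
  saturated <- ci99$lo > 0 | ci99$hi < 0
  dn <- list(basis, emotion_labels())
  out <- list(beta_mean = structure(apply(arr, c(1, 2), mean),
                                    dimnames = dn),
              ci95_lo = structure(ci95$lo, dimnames = dn),
              ci95_hi = structure(ci95$hi, dimnames = dn),
              ci99_lo = structure(ci99$lo, dimnames = dn),
              ci99_hi = structure(ci99$hi, dimnames = dn),
              saturated = structure(saturated, dimnames = dn),
              objectives = vapply(fits, function(f)
                attr(f, "fit")$objective, numeric(1)),
              n_restarts = n_restarts, fits = fits)
  class(out) <- "fit_report"
  out
}
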