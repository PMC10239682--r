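# Synthetic observer data with the statistical structure the analysis
# assumes: a generative world with a known prior over minds, a known
# sparse emotion-concept transformation, and observers whose ratings are
# noisy reflections of the model's latent quantities. Used for
# end-to-end parameter-recovery and lesion-comparison studies without
# any empirical download.

# Discretised Beta marginal on a grid.
beta_marginal <- function(grid, shape1, shape2) {
  d <- stats::dbeta(pmin(pmax(grid, 1e-3), 1 - 1e-3), shape1, shape2)
  list(values = grid, probs = d / sum(d))
}

#' Construct a synthetic world
#'
#' Fixes the complete generative state: a heterogeneous generic prior
#' over minds (discretised Beta(2,2) marginals: most players care
#' moderately about each feature, few are extreme), a sparse true
#' concept transformation (each beta weight nonzero with probability
#' `sparsity`, magnitudes uniform on `beta_range` with random sign), an
#' observer noise scale, and the condition design (four outcomes at each
#' pot). Appraisal distributions for every condition are computed and
#' standardised once and stored with their scaling record.
#'
#' @param seed integer seed fixing the true transformation.
#' @param n_omega,n_belief prior grid resolutions (kept coarse by
#'   default so the joint support stays tractable).
#' @param pots pot sizes of the design.
#' @param cfg a [planning_config()].
#' @param sparsity fraction of nonzero true beta weights (default 0.3).
#' @param beta_range magnitude range of nonzero weights.
#' @param noise_sd observer emotion noise SD (also the true kernel SD).
#' @param k logistic steepness.
#' @param n_components cap on appraisal mixture components per condition.
#' @return a `synth_world` list.
#' @export
synth_world <- function(seed = 1L, n_omega = 3L, n_belief = 4L,
                        pots = pot_grid(), cfg = planning_config(),
                        sparsity = 0.3, beta_range = c(0.5, 2),
                        noise_sd = 0.1, k = 0.4, n_components = 150L) {
  set.seed(seed)
  og <- seq(0, 1, length.out = n_omega)
  bg <- seq(0, 1, length.out = n_belief)
  marg <- list(w_money_base = beta_marginal(og, 2, 2),
               w_aia_base = beta_marginal(og, 2, 2),
               w_dia_base = beta_marginal(og, 2, 2),
               w_money_repu = beta_marginal(og, 2, 2),
               w_aia_repu = beta_marginal(og, 2, 2),
               w_dia_repu = beta_marginal(og, 2, 2),
               pi_a2 = beta_marginal(bg, 2, 2))
  prior <- grid_prior(marg, variant = "generic")
  design <- condition_design(pots)
  raw <- appraisal_set(prior, design, cfg, n_max = n_components,
                       seed = seed)
  std <- standardize_appraisals(raw)

  p <- length(appraisal_components())
  nonzero <- stats::runif(p * 20L) < sparsity
  beta_true <- matrix(0, p, 20L)
  beta_true[nonzero] <- stats::runif(sum(nonzero), beta_range[1],
                                     beta_range[2]) *
    sample(c(-1, 1), sum(nonzero), replace = TRUE)
  b_true <- logit(stats::runif(20L, 0.15, 0.45))
  transform_true <- concept_transform(beta_true, b_true,
                                      rep(noise_sd^2, 20L), k = k,
                                      scale = std$scale)
  structure(list(prior = prior, base_prior = base_marginal(prior),
                 cfg = cfg, design = design, samples = std$samples,
                 scale = std$scale, transform_true = transform_true,
                 noise_sd = noise_sd, seed = seed,
                 n_components = n_components),
            class = "synth_world")
}

#' @export
print.synth_world <- function(x, ...) {
  cat(sprintf("<synth_world: %d conditions, %d-point prior, %d nonzero beta>\n",
              nrow(x$design), nrow(x$prior$support),
              sum(x$transform_true$beta != 0)))
  invisible(x)
}

# Named sample list for the world's design (already standardised).
world_samples <- function(world) {
  stats::setNames(world$samples, world$design$key)
}

#' Generate a synthetic attribution dataset
#'
#' Each observer completes `trials_per_observer` trials (alternating
#' observed actions, pots cycled over the design grid). Per trial a mind
#' is drawn from the true posterior given the observed action, and the
#' observer reports each dimension with truncated-Normal rating noise;
#' the belief is discretised to the 6-point confidence scale.
#'
#' @param world a [synth_world()].
#' @param n_observers number of observers.
#' @param seed RNG seed.
#' @param rating_sd observer rating noise SD (default 0.1).
#' @param trials_per_observer trials per observer (default 2: one C, one
#'   D).
#' @param player_id id recorded on the rows.
#' @param prior prior to invert; defaults to the world's generic prior.
#' @return long data.frame `observer_id, player_id, a1, pot, dimension,
#'   rating`.
#' @export
generate_attribution_dataset <- function(world, n_observers, seed = 1L,
                                         rating_sd = 0.1,
                                         trials_per_observer = 2L,
                                         player_id = "generic",
                                         prior = NULL) {
  set.seed(seed)
  prior <- prior %||% world$prior
  pots <- unique(world$design$pot)
  dims_w <- c(money_base = "w_money_base", aia_base = "w_aia_base",
              dia_base = "w_dia_base", money_repu = "w_money_repu",
              aia_repu = "w_aia_repu", dia_repu = "w_dia_repu")
  posts <- list()  # cache inversions per (a1, pot)
  rows <- vector("list", n_observers * trials_per_observer)
  r <- 0L
  for (ob in seq_len(n_observers)) {
    for (t in seq_len(trials_per_observer)) {
      a1 <- c("C", "D")[(t - 1L) %% 2L + 1L]
      pot <- sample(pots, 1L)
      key <- paste0(a1, ":", pot)
      if (is.null(posts[[key]]))
        posts[[key]] <- invert(prior, a1, pot, world$cfg,
                               base_prior = world$base_prior)
      mind <- sample_player(posts[[key]], 1L)
      noisy_w <- pmin(pmax(mind[1, dims_w] +
                             stats::rnorm(6, 0, rating_sd), 0), 1)
      belief <- pmin(pmax(mind[1, "pi_a2"] +
                            stats::rnorm(1, 0, rating_sd), 0), 1)
      r <- r + 1L
      rows[[r]] <- data.frame(observer_id = ob, player_id = player_id,
                              a1 = a1, pot = pot,
                              dimension = c(names(dims_w), "pi_a2"),
                              rating = c(noisy_w,
                                         round(belief * 5) + 1),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Draw one emotion vector for a condition: pick a mixture component by
# weight, add Gaussian observer noise, clip to [0,1].
draw_emotions <- function(sample, transform, noise_sd) {
  i <- sample.int(nrow(sample$psi), 1L, prob = sample$weights)
  mu <- inv_logit(transform$k *
                    (sample$psi[i, transform$basis, drop = FALSE] %*%
                       transform$beta) + transform$b)
  pmin(pmax(as.numeric(mu) + stats::rnorm(20L, 0, noise_sd), 0), 1)
}

#' Generate a synthetic emotion-prediction dataset
#'
#' Emulates the generic training design: each observer completes eight
#' trials, two per outcome class, with pots drawn from the design grid.
#' Per trial an appraisal vector is sampled from the condition's
#' posterior appraisal distribution and the reported emotion vector is
#' the true transformation's logistic mean plus Gaussian noise, clipped
#' to \[0, 1\].
#'
#' @param world a [synth_world()].
#' @param n_observers number of observers (the generic training study
#'   used 554).
#' @param trials_per_observer trials each (default 8; must be a multiple
#'   of 4).
#' @param seed RNG seed.
#' @param samples appraisal samples to draw from (default: the world's
#'   generic samples); pass a specific player's samples for test data.
#' @param transform true transformation (default: the world's).
#' @param player_id id recorded on the rows.
#' @return data.frame `observer_id, player_id, a1, a2, pot` + 20 emotion
#'   columns.
#' @export
generate_emotion_dataset <- function(world, n_observers,
                                     trials_per_observer = 8L, seed = 1L,
                                     samples = NULL, transform = NULL,
                                     player_id = "generic") {
  stopifnot(trials_per_observer %% 4L == 0L)
  set.seed(seed)
  samples <- samples %||% world_samples(world)
  transform <- transform %||% world$transform_true
  design <- world$design
  per_oc <- trials_per_observer %/% 4L
  n <- n_observers * trials_per_observer
  E <- matrix(NA_real_, n, 20L,
              dimnames = list(NULL, emotion_labels()))
  meta <- data.frame(observer_id = integer(n), player_id = player_id,
                     a1 = character(n), a2 = character(n),
                     pot = numeric(n), stringsAsFactors = FALSE)
  r <- 0L
  for (ob in seq_len(n_observers)) {
    for (oc in c("CC", "CD", "DC", "DD")) {
      rows_oc <- which(substr(design$key, 1, 2) == oc)
      picks <- sample(rows_oc, per_oc, replace = per_oc > length(rows_oc))
      for (i in picks) {
        r <- r + 1L
        meta$observer_id[r] <- ob
        meta$a1[r] <- design$a1[i]; meta$a2[r] <- design$a2[i]
        meta$pot[r] <- design$pot[i]
        E[r, ] <- draw_emotions(samples[[design$key[i]]], transform,
                                world$noise_sd)
      }
    }
  }
  cbind(meta, as.data.frame(E))
}

#' Generate synthetic specific players
#'
#' Each player's prior is the generic prior exponentially tilted along
#' the mind dimensions: log-weights receive `support %*% gamma` with
#' `gamma ~ N(0, perturb_scale^2)` per dimension, then renormalised.
#' (Unstructured i.i.d. point noise would average out under
#' marginalisation and produce no systematic player differences; tilting
#' shifts the marginal means the way a personalising description would.)
#' Per player the appraisal distributions are recomputed under the
#' personalised prior, standardised with the world's training scaling
#' record, and an emotion dataset is drawn from the true transformation.
#'
#' @param world a [synth_world()].
#' @param m_players number of players (default 20).
#' @param perturb_scale tilt SD; 0 reproduces the generic prior exactly.
#' @param n_observers observers per player's emotion dataset.
#' @param trials_per_observer trials per observer (default 8).
#' @param seed RNG seed.
#' @return named list per player: `prior`, `samples` (standardised),
#'   `emotion_data`.
#' @export
generate_specific_players <- function(world, m_players = 20L,
                                      perturb_scale = 1,
                                      n_observers = 20L,
                                      trials_per_observer = 8L,
                                      seed = 1L) {
  set.seed(seed)
  dims <- mind_dimensions()
  players <- list()
  for (m in seq_len(m_players)) {
    pid <- sprintf("P%02d", m)
    gamma <- stats::rnorm(length(dims), 0, perturb_scale)
    tilt <- as.numeric(world$prior$support[, dims] %*% gamma)
    lw <- log(world$prior$weights) + tilt
    w <- exp(lw - logsumexp(lw))
    sp <- mind_prior(world$prior$support, w, variant = "specific",
                     player_id = pid)
    raw <- appraisal_set(sp, world$design, world$cfg,
                         base_prior = world$base_prior,
                         n_max = world$n_components,
                         seed = seed + 1000L * m)
    std <- standardize_appraisals(raw, scale = world$scale)
    emo <- generate_emotion_dataset(world, n_observers,
                                    trials_per_observer,
                                    seed = seed + 2000L + m,
                                    samples = stats::setNames(
                                      std$samples, world$design$key),
                                    player_id = pid)
    players[[pid]] <- list(player_id = pid, prior = sp,
                           samples = stats::setNames(std$samples,
                                                     world$design$key),
                           emotion_data = emo)
  }
  players
}
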