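# Unit tests for the emotion-concept transformation, its likelihood and
# the MAP fitting machinery. Heavy end-to-end recovery lives in
# test-acceptance.R.

toy_sample <- function(psi, w = NULL) {
  w <- w %||% rep(1 / nrow(psi), nrow(psi))
  structure(list(psi = psi, weights = w,
                 condition = list(a1 = "C", a2 = "C", pot = 1),
                 scale = rep(1, ncol(psi))),
            class = "appraisal_sample")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rand_psi <- function(n, seed = 1) {
  set.seed(seed)
  psi <- matrix(rnorm(n * 19), n, 19,
                dimnames = list(NULL, appraisal_components()))
  psi
}

test_that("predict_emotions implements the logistic link", {
  b <- seq(-1, 1, length.out = 20)
  # beta = 0: expectation is the inverse-logit of the intercepts
  t0 <- concept_transform(matrix(0, 19, 20), b, rep(0.01, 20))
  p <- predict_emotions(t0, toy_sample(rand_psi(7)))
  expect_equal(unname(p$expectation), plogis(b), tolerance = 1e-12)
  expect_true(all(p$means > 0 & p$means < 1))
  # single-sample closed form at k = 0.4
  beta <- matrix(0, 19, 20); beta[3, 5] <- 1.5
  t1 <- concept_transform(beta, b, rep(0.01, 20))
  psi <- rand_psi(1, seed = 2)
  p1 <- predict_emotions(t1, toy_sample(psi))
  expect_equal(unname(p1$expectation[5]),
               unname(plogis(0.4 * 1.5 * psi[1, 3] + b[5])),
               tolerance = 1e-12)
  # monotonicity through a positive weight
  psi_hi <- psi; psi_hi[1, 3] <- psi[1, 3] + 1
  p2 <- predict_emotions(t1, toy_sample(psi_hi))
  expect_gt(p2$expectation[5], p1$expectation[5])
})

test_that("mixture likelihood reduces to a Gaussian for N = 1", {
  beta <- matrix(rnorm(19 * 20, 0, 0.3), 19, 20)
  b <- rnorm(20); s2 <- runif(20, 0.005, 0.05)
  tr <- concept_transform(beta, b, s2)
  psi <- rand_psi(1, seed = 3)
  s <- toy_sample(psi)
  key <- splitsteal:::condition_key("C", "C", 1)
  set.seed(4)
  e <- runif(20)
  d <- cbind(data.frame(a1 = "C", a2 = "C", pot = 1),
             as.data.frame(matrix(e, 1, 20,
                                  dimnames = list(NULL, emotion_labels()))))
  mu <- plogis(0.4 * psi %*% beta + rep(b, each = 1))
  want <- sum(dnorm(e, as.numeric(mu), sqrt(s2), log = TRUE))
  got <- log_likelihood(tr, d, setNames(list(s), key))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("duplicating mixture components leaves the likelihood unchanged", {
  tr <- concept_transform(matrix(rnorm(19 * 20, 0, 0.2), 19, 20),
                          rnorm(20), runif(20, 0.01, 0.05))
  psi <- rand_psi(6, seed = 5)
  s <- toy_sample(psi)
  s_dup <- toy_sample(rbind(psi, psi))
  key <- splitsteal:::condition_key("C", "C", 1)
  set.seed(6)
  d <- cbind(data.frame(a1 = rep("C", 4), a2 = "C", pot = 1),
             as.data.frame(matrix(runif(80), 4, 20,
                                  dimnames = list(NULL, emotion_labels()))))
  expect_equal(log_likelihood(tr, d, setNames(list(s), key)),
               log_likelihood(tr, d, setNames(list(s_dup), key)),
               tolerance = 1e-12)
})

test_that("two-component mixture matches hand-computed density", {
  beta <- matrix(0, 19, 20)
  b <- rep(0, 20); s2 <- rep(0.04, 20)
  beta[1, 1] <- 2; beta[2, 2] <- -1
  tr <- concept_transform(beta, b, s2)
  psi <- rand_psi(2, seed = 7)
  s <- toy_sample(psi, w = c(0.5, 0.5))
  set.seed(8)
  e <- runif(20)
  d <- cbind(data.frame(a1 = "C", a2 = "C", pot = 1),
             as.data.frame(matrix(e, 1, 20,
                                  dimnames = list(NULL, emotion_labels()))))
  comp <- function(i) {
    mu <- plogis(0.4 * as.numeric(psi[i, ] %*% beta) + b)
    sum(dnorm(e, mu, sqrt(s2), log = TRUE))
  }
  want <- log(0.5 * exp(comp(1)) + 0.5 * exp(comp(2)))
  key <- splitsteal:::condition_key("C", "C", 1)
  expect_equal(log_likelihood(tr, d, setNames(list(s), key)), want,
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  set.seed(9)
  psi <- rand_psi(4, seed = 9)
  s <- toy_sample(psi)
  key <- splitsteal:::condition_key("C", "C", 1)
  d <- cbind(data.frame(a1 = rep("C", 3), a2 = "C", pot = 1),
             as.data.frame(matrix(runif(60, 0.2, 0.8), 3, 20,
                                  dimnames = list(NULL, emotion_labels()))))
  blocks <- splitsteal:::prepare_concept_data(d, setNames(list(s), key))
  theta <- list(beta = matrix(rnorm(19 * 20, 0, 0.2), 19, 20),
                b = rnorm(20, 0, 0.5), logs2 = log(runif(20, 0.02, 0.1)))
  og <- splitsteal:::mixture_obj_grad(theta, blocks, 0.4)
  f <- function(th) splitsteal:::mixture_obj_grad(th, blocks, 0.4,
                                                  grad = FALSE)$ll
  h <- 1e-6
  for (probe in list(c("beta", 5, 3), c("beta", 17, 20), c("b", 11, NA),
                     c("logs2", 4, NA))) {
    th1 <- theta; th2 <- theta
    nm <- probe[1]; i <- as.integer(probe[2])
    if (nm == "beta") {
      j <- as.integer(probe[3])
      th1$beta[i, j] <- th1$beta[i, j] + h
      th2$beta[i, j] <- th2$beta[i, j] - h
      want <- og$gbeta[i, j]
    } else {
      th1[[nm]][i] <- th1[[nm]][i] + h
      th2[[nm]][i] <- th2[[nm]][i] - h
      want <- if (nm == "b") og$gb[i] else og$glogs2[i]
    }
    expect_equal((f(th1) - f(th2)) / (2 * h), unname(want),
                 tolerance = 1e-4)
  }
})

test_that("fit_concepts obeys prior-dominance limits and KKT optimality", {
  w <- tiny_world()
  d <- generate_emotion_dataset(w, 40, 8, seed = 10)
  gs <- splitsteal:::world_samples(w)
  ctrl <- fit_control(max_iter = 5000, tol = 1e-10)
  # very strong prior drives every weight to exactly zero
  f_small <- fit_concepts(d, gs, tau = 1e-3, seed = 1, control = ctrl)
  expect_true(all(f_small$beta == 0))
  p <- predict_emotions(f_small, gs[[1]])
  expect_equal(unname(p$expectation), unname(plogis(f_small$b)),
               tolerance = 1e-12)
  # KKT conditions at the optimum (independent optimality oracle):
  # |grad_ll| <= pen on zero weights, grad_ll = -pen * sign(beta) + 0
  # on active weights
  f <- suppressWarnings(fit_concepts(d, gs, tau = 50, seed = 1,
                                     control = ctrl))
  blocks <- splitsteal:::prepare_concept_data(d, gs)
  theta <- list(beta = unname(f$beta), b = unname(f$b),
                logs2 = log(unname(f$sigma2)))
  og <- splitsteal:::mixture_obj_grad(theta, blocks, f$k)
  pen <- nrow(d) / 50
  gscale <- max(abs(og$gbeta), pen)
  active <- f$beta != 0
  expect_gt(sum(active), 0)
  expect_gt(sum(!active), 0)
  expect_lt(max(abs(og$gbeta[active] - pen * sign(f$beta[active]))),
            0.02 * gscale)
  expect_lt(max(abs(og$gbeta[!active])), pen * 1.02)
  expect_lt(max(abs(og$gb)), 0.02 * gscale)
  # objective trace is non-decreasing over accepted steps
  tr <- attr(f, "fit")$trace
  expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)))
})

test_that("weak penalty approaches the unpenalised fit", {
  w <- tiny_world()
  d <- generate_emotion_dataset(w, 25, 8, seed = 11)
  gs <- splitsteal:::world_samples(w)
  ctrl <- fit_control(max_iter = 2500, tol = 1e-9)
  f1 <- suppressWarnings(fit_concepts(d, gs, tau = 1e6, seed = 2,
                                      control = ctrl))
  f2 <- suppressWarnings(fit_concepts(d, gs, tau = 1e8, seed = 2,
                                      control = ctrl))
  ll1 <- log_likelihood(f1, d, gs)
  ll2 <- log_likelihood(f2, d, gs)
  expect_lt(abs(ll1 - ll2) / (abs(ll2) + 1), 5e-3)
})

test_that("shared appraisals induce cross-emotion prediction covariance", {
  beta <- matrix(0, 19, 20)
  beta[1, 1] <- 2; beta[1, 2] <- 2   # two emotions driven by one appraisal
  tr <- concept_transform(beta, rep(0, 20), rep(0.01, 20))
  p <- predict_emotions(tr, toy_sample(rand_psi(200, seed = 12)))
  expect_gt(cov(p$means[, 1], p$means[, 2]), 0.01)
  expect_lt(abs(cov(p$means[, 1], p$means[, 3])), 1e-6)
})

test_that("tau cross-validation partitions players correctly", {
  w <- tiny_world()
  d <- generate_emotion_dataset(w, 25, 8, seed = 13)
  gs <- splitsteal:::world_samples(w)
  players <- generate_specific_players(w, 6, perturb_scale = 1,
                                       n_observers = 5, seed = 14)
  sdata <- do.call(rbind, lapply(players, `[[`, "emotion_data"))
  ssamp <- lapply(players, `[[`, "samples")
  ctrl <- fit_control(max_iter = 300, tol = 1e-6)
  # single-value grid: selected trivially, every player predicted once
  cv <- select_tau_cv(d, gs, sdata, ssamp, tau_grid = 50, fold_size = 2L,
                      seed = 3, control = ctrl)
  expect_true(all(cv$selected_tau == 50))
  held <- unlist(lapply(cv$folds, `[[`, "players"))
  expect_setequal(held, names(players))
  expect_identical(anyDuplicated(held), 0L)
  expect_setequal(names(cv$predictions), names(players))
  # uneven fold size warns
  expect_warning(
    select_tau_cv(d, gs, sdata, ssamp, tau_grid = 50, fold_size = 4L,
                  seed = 3, control = ctrl), "fold")
})

test_that("restart confidence intervals are nested and ordered", {
  w <- tiny_world()
  d <- generate_emotion_dataset(w, 25, 8, seed = 15)
  gs <- splitsteal:::world_samples(w)
  rep <- beta_confidence(d, gs, tau = 50, n_restarts = 5, seed = 4,
                         control = fit_control(max_iter = 300,
                                               tol = 1e-6))
  expect_true(all(rep$ci99_lo <= rep$ci95_lo + 1e-12))
  expect_true(all(rep$ci95_hi <= rep$ci99_hi + 1e-12))
  expect_true(all(rep$ci95_lo <= rep$beta_mean + 1e-12))
  # saturation never flags an interval that straddles zero
  straddle <- rep$ci99_lo <= 0 & rep$ci99_hi >= 0
  expect_true(!any(rep$saturated & straddle))
})

test_that("social-lesion fits use the restricted basis", {
  w <- tiny_world()
  d <- generate_emotion_dataset(w, 25, 8, seed = 16)
  gs <- splitsteal:::world_samples(w)
  f <- fit_concepts(d, gs, tau = 50, basis = social_lesion_basis(),
                    seed = 5, control = fit_control(max_iter = 300,
                                                    tol = 1e-6))
  expect_identical(rownames(f$beta), social_lesion_basis())
  expect_identical(dim(f$beta), c(2L, 20L))
  p <- predict_emotions(f, gs[[3]])
  expect_length(p$expectation, 20L)
})
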