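# Emotion-concept transformations: a sparse linear map from standardised
# appraisal space through a logistic link to 20 emotion intensities, with
# a uniformly weighted Gaussian-mixture likelihood over the latent
# appraisal samples of each game condition.

#' Construct an emotion-concept transformation
#'
#' @param beta p x 20 weight matrix (appraisal component -> emotion); p
#'   is the length of `basis`.
#' @param b length-20 intercept vector.
#' @param sigma2 length-20 per-emotion variance vector (> 0).
#' @param k logistic steepness constant (default 0.4).
#' @param tau Laplace scale used during fitting (NA if unfitted).
#' @param basis appraisal component names the transform operates on;
#'   defaults to the full 19-component basis.
#' @param scale the appraisal scaling record the transform was trained
#'   with (divisors applied to raw appraisals).
#' @return a `concept_transform` object.
#' @export
concept_transform <- function(beta, b, sigma2, k = 0.4, tau = NA_real_,
                              basis = appraisal_components(), scale = NULL) {
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == length(basis), ncol(beta) == 20L,
            length(b) == 20L, length(sigma2) == 20L)
  stop_if(any(sigma2 <= 0), "sigma2 must be strictly positive")
  stop_if(k <= 0, "k must be positive")
  dimnames(beta) <- list(basis, emotion_labels())
  structure(list(beta = beta, b = stats::setNames(as.numeric(b),
                                                  emotion_labels()),
                 sigma2 = stats::setNames(as.numeric(sigma2),
                                          emotion_labels()),
                 k = k, tau = tau, basis = basis, scale = scale),
            class = "concept_transform")
}

#' @export
print.concept_transform <- function(x, ...) {
  nz <- sum(abs(x$beta) > 0)
  cat(sprintf("<concept_transform: %d x 20, %d nonzero weights, tau = %s>\n",
              nrow(x$beta), nz, format(x$tau)))
  invisible(x)
}

# Subset an appraisal matrix to the transform's basis.
psi_basis <- function(psi, basis) {
  stopifnot(all(basis %in% colnames(psi)))
  psi[, basis, drop = FALSE]
}

#' Predict emotions from an appraisal sample
#'
#' Each appraisal sample point maps to a mean emotion vector
#' `mu = logit^-1(k * psi * beta + b)`; the condition-level prediction is
#' the weighted mixture expectation of these means.
#'
#' @param transform a [concept_transform()].
#' @param sample an `appraisal_sample`, standardised with the training
#'   scaling record.
#' @return list with `means` (n x 20 matrix of per-sample means),
#'   `weights`, and `expectation` (length-20 mixture expectation); all
#'   values in (0, 1).
#' @export
predict_emotions <- function(transform, sample) {
  stopifnot(inherits(transform, "concept_transform"),
            inherits(sample, "appraisal_sample"))
  psi <- psi_basis(sample$psi, transform$basis)
  eta <- transform$k * (psi %*% transform$beta)
  eta <- sweep(eta, 2, transform$b, "+")
  mu <- inv_logit(eta)
  colnames(mu) <- emotion_labels()
  list(means = mu, weights = sample$weights,
       expectation = colSums(mu * sample$weights))
}

# ---- Gaussian-mixture likelihood engine ------------------------------

# Bundle an emotion dataset with per-condition appraisal samples into the
# per-condition blocks the objective/gradient engine consumes.
prepare_concept_data <- function(data, samples, basis = appraisal_components()) {
  stopifnot(is.data.frame(data))
  emo <- emotion_labels()
  stop_if(!all(emo %in% names(data)), "dataset must have 20 emotion columns")
  keys <- condition_key(data$a1, data$a2, data$pot)
  blocks <- lapply(split(seq_len(nrow(data)), keys), function(ix) {
    key <- keys[ix[1]]
    s <- samples[[key]]
    stop_if(is.null(s), paste("no appraisal sample for condition", key))
    list(E = as.matrix(data[ix, emo, drop = FALSE]),
         psi = psi_basis(s$psi, basis),
         logw = log(s$weights))
  })
  blocks
}

# Log-likelihood and (optionally) gradients of the mixture model.
# theta: list(beta p x 20, b 20, logs2 20). Returns list(ll, gbeta, gb,
# glogs2). All computation is in the log domain via log-sum-exp.
mixture_obj_grad <- function(theta, blocks, k, grad = TRUE) {
  beta <- theta$beta; b <- theta$b; s2 <- exp(theta$logs2)
  inv_s2 <- 1 / s2
  log_norm <- -0.5 * sum(log(2 * pi * s2))
  ll <- 0
  gbeta <- if (grad) matrix(0, nrow(beta), ncol(beta)) else NULL
  gb <- if (grad) numeric(20) else NULL
  gs <- if (grad) numeric(20) else NULL
  for (blk in blocks) {
    E <- blk$E
    mu <- inv_logit(sweep(k * (blk$psi %*% beta), 2, b, "+"))  # N x 20
    Es <- sweep(E, 2, inv_s2, "*")                             # m x 20
    a_r <- -0.5 * rowSums(sweep(E^2, 2, inv_s2, "*"))          # m
    c_i <- -0.5 * rowSums(sweep(mu^2, 2, inv_s2, "*"))         # N
    D <- Es %*% t(mu)                                          # m x N
    D <- sweep(D, 1, a_r, "+")
    D <- sweep(D, 2, c_i + blk$logw, "+")
    L_r <- row_logsumexp(D)
    ll <- ll + sum(L_r) + nrow(E) * log_norm
    if (grad) {
      R <- exp(D - L_r)                                        # m x N resp.
      cs <- colSums(R)                                         # N
      TRE <- t(R) %*% E                                        # N x 20
      dmu <- sweep(TRE - cs * mu, 2, inv_s2, "*")              # N x 20
      G <- dmu * mu * (1 - mu)
      gbeta <- gbeta + k * (t(blk$psi) %*% G)
      gb <- gb + colSums(G)
      S <- colSums(E^2) - 2 * colSums(TRE * mu) + colSums(cs * mu^2)
      gs <- gs + 0.5 * (S * inv_s2 - nrow(E))
    }
  }
  list(ll = ll, gbeta = gbeta, gb = gb, glogs2 = gs)
}

#' Mixture log-likelihood of an emotion dataset
#'
#' `sum_e log[(1/N) sum_i N(e; logit^-1(k psi_i beta + b), diag(sigma2))]`
#' with the mixture over the appraisal sample of the row's game
#' condition (weights generalise the uniform 1/N to a deduplicated
#' weighted support).
#'
#' @param transform a [concept_transform()].
#' @param data emotion dataset: data.frame with `a1, a2, pot` and the 20
#'   emotion columns.
#' @param samples named list of standardised `appraisal_sample`s keyed by
#'   `condition_key(a1, a2, pot)` (see [appraisal_set()]).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(transform, data, samples) {
  blocks <- prepare_concept_data(data, samples, transform$basis)
  theta <- list(beta = transform$beta, b = transform$b,
                logs2 = log(transform$sigma2))
  mixture_obj_grad(theta, blocks, transform$k, grad = FALSE)$ll
}
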