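# Model-human agreement: Lin's concordance correlation, bootstrap
# confidence intervals, and the personalization-bias analysis comparing a
# model's predicted specific-vs-generic emotion differences with the
# empirical differences.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Penalises decorrelation and location/scale
#' shift; equals 1 only for `y = x`.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return concordance in \[-1, 1\]; 0 (with a warning) if both inputs
#'   are constant.
#' @export
lin_ccc <- function(x, y) {
  stop_if(length(x) != length(y), "x and y must have equal length")
  stopifnot(length(x) >= 2L)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  if (vx <= .Machine$double.eps && vy <= .Machine$double.eps) {
    warning("lin_ccc: constant inputs; returning 0")
    return(0)
  }
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (or clusters, e.g. observers) of `data` with
#' replacement and returns the percentile interval of the statistic.
#'
#' @param statistic function of one argument (the resampled data)
#'   returning a numeric scalar.
#' @param data data.frame or vector to resample.
#' @param B number of bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @param groups optional vector of cluster ids (one per row); when
#'   given, whole clusters are resampled (cluster bootstrap).
#' @return named vector `c(lo, hi)` with attribute `estimate` (the
#'   statistic on the original data).
#' @export
bootstrap_ci <- function(statistic, data, B = 1000L, seed = 1L,
                         level = 0.95, groups = NULL) {
  set.seed(seed)
  take <- function(idx) if (is.data.frame(data))
    data[idx, , drop = FALSE] else data[idx]
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stats_b <- numeric(B)
  if (is.null(groups)) {
    for (b in seq_len(B))
      stats_b[b] <- statistic(take(sample.int(n, n, replace = TRUE)))
  } else {
    stopifnot(length(groups) == n)
    gidx <- split(seq_len(n), groups)
    for (b in seq_len(B)) {
      gs <- sample(length(gidx), length(gidx), replace = TRUE)
      stats_b[b] <- statistic(take(unlist(gidx[gs], use.names = FALSE)))
    }
  }
  a <- (1 - level) / 2
  ci <- stats::quantile(stats_b, c(a, 1 - a), names = FALSE)
  out <- c(lo = ci[1], hi = ci[2])
  attr(out, "estimate") <- statistic(data)
  attr(out, "replicates") <- stats_b
  out
}

#' Personalization bias vector
#'
#' The per-(outcome x emotion) difference between a specific player's
#' expected emotions and the generic expectation,
#' `delta = E[emotion | outcome; player] - E[emotion | outcome; generic]`,
#' flattened over the four outcome classes and 20 emotions (80 entries).
#' Applies equally to empirical expectations and to a model's own
#' predictions (each model's bias is computed relative to its own
#' generic prediction).
#'
#' @param specific,generic 4 x 20 matrices (rows CC, CD, DC, DD).
#' @return named numeric vector of length 80.
#' @export
emotion_bias <- function(specific, generic) {
  stopifnot(is.matrix(specific), is.matrix(generic),
            all(dim(specific) == c(4L, 20L)),
            all(dim(generic) == c(4L, 20L)))
  d <- specific - generic
  stats::setNames(as.numeric(d),
                  as.character(outer(c("CC", "CD", "DC", "DD"),
                                     emotion_labels(), paste, sep = ".")))
}

#' Agreement between model and empirical bias vectors
#'
#' @param model_bias,empirical_bias length-80 vectors from
#'   [emotion_bias()] (or any equal-length pair).
#' @return named vector with `ccc`, `pearson`, and `scaled_pearson` (the
#'   variance-scaled Pearson correlation: Pearson r multiplied by
#'   `min(1, sd(model)/sd(empirical))`, so a model that under-disperses
#'   its personalization is penalised).
#' @export
bias_correlation <- function(model_bias, empirical_bias) {
  stop_if(length(model_bias) != length(empirical_bias),
          "bias vectors must have equal length")
  r <- if (stats::sd(model_bias) == 0 || stats::sd(empirical_bias) == 0)
    0 else stats::cor(model_bias, empirical_bias)
  scl <- if (stats::sd(empirical_bias) == 0) 0 else
    min(1, stats::sd(model_bias) / stats::sd(empirical_bias))
  c(ccc = lin_ccc(model_bias, empirical_bias), pearson = r,
    scaled_pearson = r * scl)
}

#' Average per-condition expectations over pots within outcome class
#'
#' @param mat matrix with rownames of the form `"<a1><a2>:<pot>"` (as
#'   produced by [predict_condition_expectations()]).
#' @return 4 x 20 matrix with rows CC, CD, DC, DD.
#' @export
outcome_expectations <- function(mat) {
  oc <- substr(rownames(mat), 1, 2)
  out <- rowsum(mat, oc) / as.numeric(table(oc)[sort(unique(oc))])
  out[c("CC", "CD", "DC", "DD"), , drop = FALSE]
}

#' Evaluate a model's predictions against empirical data
#'
#' Convenience wrapper producing an evaluation report: overall and
#' per-emotion concordance between per-condition predicted expectations
#' and empirical means, with an optional bootstrap CI over observers.
#'
#' @param predicted matrix of per-condition expectations (rows keyed by
#'   condition).
#' @param data emotion dataset covering the same conditions.
#' @param B bootstrap resamples for the overall ccc CI (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return list with `ccc`, `ccc_ci`, and `per_emotion` (named vector of
#'   per-emotion concordances).
#' @export
evaluate_predictions <- function(predicted, data, B = 0L, seed = 1L) {
  emp <- empirical_condition_means(data)
  common <- intersect(rownames(predicted), rownames(emp))
  stop_if(length(common) == 0L, "no shared conditions to evaluate")
  pred <- predicted[common, , drop = FALSE]
  overall <- lin_ccc(as.numeric(pred), as.numeric(emp[common, ]))
  per_emotion <- vapply(emotion_labels(), function(e)
    lin_ccc(pred[, e], emp[common, e]), numeric(1))
  ci <- NULL
  if (B > 0L) {
    stat <- function(d) {
      m <- empirical_condition_means(d)
      cm <- intersect(rownames(predicted), rownames(m))
      lin_ccc(as.numeric(predicted[cm, , drop = FALSE]),
              as.numeric(m[cm, , drop = FALSE]))
    }
    ci <- bootstrap_ci(stat, data, B = B, seed = seed,
                       groups = data$observer_id)
  }
  list(ccc = overall, ccc_ci = ci, per_emotion = per_emotion)
}
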