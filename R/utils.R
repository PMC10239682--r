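# Internal numerical helpers shared across modules.

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# Weighted mean with weights assumed to sum to 1.
wmean <- function(x, w) sum(x * w)

# Population-style weighted standard deviation (weights sum to 1).
wsd <- function(x, w) {
  mu <- sum(x * w)
  sqrt(max(sum(w * (x - mu)^2), 0))
}

#' Inverse logit
#' @param x numeric.
#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
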