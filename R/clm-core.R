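## Core cumulative link (proportional-odds) model math. Everything here is a
## pure function of CLMParameters and data; inference lives in clm-inference.

## Linear predictor x'beta for one covariate vector.
.linpred <- function(params, x) {
  x <- as.numeric(x)
  if (length(x) != length(params@beta))
    stop("covariate vector length must match length(beta)")
  if (any(!is.finite(x))) stop("covariates must be finite")
  sum(x * params@beta)
}

## n x J matrix of log class probabilities for a vector of single-covariate
## observations; used by likelihood and deviance code paths. theta/beta are
## raw numerics so the sampler can call it without constructing S4 objects.
.logClassProbMatrix <- function(theta, beta, scores) {
  J <- length(theta) + 1L
  eta <- outer(as.numeric(scores) * beta, rep(1, J))
  a <- matrix(c(theta, Inf), nrow = length(scores), ncol = J, byrow = TRUE) - eta
  b <- matrix(c(-Inf, theta), nrow = length(scores), ncol = J, byrow = TRUE) - eta
  matrix(.logSigmoidDiff(a, b), nrow = length(scores), ncol = J)
}

#' Cumulative class probabilities of the proportional-odds model
#'
#' Evaluates \eqn{\gamma_j = P(Y \le j) = logit^{-1}(\theta_j - x^\top\beta)}
#' for j = 1..J-1 and \eqn{\gamma_J = 1}.
#'
#' @param params a \linkS4class{CLMParameters}.
#' @param x covariate vector for one observation (length = length(beta)).
#' @return Numeric vector of J non-decreasing cumulative probabilities,
#'   ending in 1.
#' @examples
#' p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 0)
#' cumulativeProbs(p, 0)   # logistic CDF at the cut-offs
#' @export
cumulativeProbs <- function(params, x) {
  eta <- .linpred(params, x)
  c(plogis(params@theta - eta), 1)
}

#' Class membership probabilities under the cumulative link model
#'
#' First differences of the cumulative probabilities:
#' \eqn{P(Y = j) = \gamma_j - \gamma_{j-1}}, computed via numerically stable
#' log-sigmoid differences so that extreme scores (scaled scores can reach
#' the hundreds for structural variants) do not underflow to qualitatively
#' wrong zeros.
#'
#' @inheritParams cumulativeProbs
#' @return List with \code{probs} (length J, sums to 1) and
#'   \code{cumulative} (length J, non-decreasing, ends at 1).
#' @examples
#' p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 0)
#' classProbs(p, 0)$probs
#' @export
classProbs <- function(params, x) {
  eta <- .linpred(params, x)
  logp <- .logSigmoidDiff(c(params@theta, Inf) - eta,
                          c(-Inf, params@theta) - eta)
  probs <- exp(logp)
  list(probs = probs, cumulative = pmin(cumsum(probs), 1))
}

#' Log-likelihood of a variant set under fixed parameters
#'
#' Each record contributes \eqn{\log P(Y_i = y_i \mid x_i)} under the
#' categorical likelihood of the cumulative link model.
#'
#' @param params a \linkS4class{CLMParameters}.
#' @param vs a \linkS4class{VariantSet} whose records all carry a score and
#'   an expert class (see \code{\link{fitSubset}}).
#' @return A single number \eqn{\le 0}; \code{-Inf} when any observed class
#'   has probability zero.
#' @export
logLikelihood <- function(params, vs) {
  rec <- variantRecords(vs)
  if (nrow(rec) == 0L) {
    warning("empty variant set: log-likelihood of an empty product is 0")
    return(0)
  }
  if (anyNA(rec$expert_class) || anyNA(rec$score))
    stop("all records must have expert_class and score; apply fitSubset() first")
  logp <- .logClassProbMatrix(params@theta, params@beta, rec$score)
  sum(logp[cbind(seq_len(nrow(rec)), rec$expert_class)])
}

#' Deviance of a single observation
#'
#' \eqn{D(Y_i) = -2 \log P(Y_i \mid \hat\theta, \hat\beta)}: a measure of how
#' surprising the expert class is to the fitted model. Zero iff the observed
#' class has probability one; \code{Inf} for a structurally impossible
#' class (under the logit link probabilities never reach zero exactly, so
#' extreme observations get large finite deviances computed in log space).
#'
#' @param params a \linkS4class{CLMParameters}.
#' @param score the observation's score.
#' @param expertClass the observation's ordinal class in 1..J.
#' @return Non-negative deviance.
#' @examples
#' p <- CLMParameters(theta = 0, beta = 0)  # J = 2, P = 0.5 each
#' observationDeviance(p, 0, 1L)            # 2 log 2
#' @export
observationDeviance <- function(params, score, expertClass) {
  J <- length(params@theta) + 1L
  stopifnot(expertClass >= 1L, expertClass <= J)
  logp <- .logClassProbMatrix(params@theta, params@beta, score)
  -2 * logp[1L, expertClass]
}

#' Model-preferred class for a score
#'
#' The class with the highest membership probability; exact ties resolve to
#' the lower class index.
#'
#' @inheritParams cumulativeProbs
#' @return Integer class in 1..J.
#' @export
assignClass <- function(params, x) {
  probs <- classProbs(params, x)$probs
  which.max(probs)  # which.max takes the first maximum: lower index on ties
}
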