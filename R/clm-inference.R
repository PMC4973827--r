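## Bayesian inference for the cumulative link model.
##
## Sampler: random-walk Metropolis-within-Gibbs on an unconstrained
## parameterization (theta_1, log-increments of theta, beta), with
## per-coordinate step sizes adapted during burn-in only. Scores are
## centred/scaled internally for mixing (scaled scores span roughly -4 to
## several hundred) and every stored draw is back-transformed to the
## original score scale. Any correct MCMC over this posterior is
## exchangeable with this one; the ML fit is the independent cross-check.

#' @importFrom stats dnorm optim qnorm quantile rnorm runif sd var median cor pnorm
NULL

#' Default sampler configuration
#'
#' @param nChains number of chains (>= 2 for PSRF).
#' @param nIter iterations per chain, including burn-in.
#' @param nBurnin burn-in iterations discarded (and used for step-size
#'   adaptation).
#' @param seed integer global seed; mandatory for every fit.
#' @param priorSd prior scale: beta ~ Normal(0, priorSd), theta_1 ~
#'   Normal(0, priorSd), cut-off increments ~ Half-Normal(priorSd). Vague
#'   but proper; at n in the thousands the likelihood dominates.
#' @param psrfThreshold convergence threshold on the split potential scale
#'   reduction factor (default 1.05).
#' @param priorOnly debug switch: drop the likelihood and sample the prior.
#' @return A named list of sampler settings.
#' @export
clmControl <- function(nChains = 4L, nIter = 5000L, nBurnin = 2500L,
                       seed = NULL, priorSd = 10, psrfThreshold = 1.05,
                       priorOnly = FALSE) {
  stopifnot(nIter > nBurnin)
  list(nChains = as.integer(nChains), nIter = as.integer(nIter),
       nBurnin = as.integer(nBurnin), seed = seed, priorSd = priorSd,
       psrfThreshold = psrfThreshold, priorOnly = isTRUE(priorOnly))
}

## Vectorized log-likelihood contributions: sum_i log P(Y_i = y_i | x_i).
## Overflowing cut-offs (exp of a large log-increment during optimization)
## mean a degenerate model: likelihood 0.
.clmLoglik <- function(theta, beta, x, y) {
  if (any(!is.finite(theta)) || any(!is.finite(beta))) return(-Inf)
  ext <- c(-Inf, theta, Inf)
  eta <- x * beta
  sum(.logSigmoidDiff(ext[y + 1L] - eta, ext[y] - eta))
}

## phi = (theta1, log diff(theta)..., beta) <-> (theta, beta)
.phiToParams <- function(phi, nTheta) {
  theta <- cumsum(c(phi[1L], exp(phi[seq_len(nTheta - 1L) + 1L])))
  list(theta = theta, beta = phi[-seq_len(nTheta)])
}

.logPrior <- function(phi, nTheta, priorSd) {
  lp <- dnorm(phi[1L], 0, priorSd, log = TRUE)
  if (nTheta > 1L) {
    logd <- phi[2L:nTheta]
    # half-normal on the increment, plus the log-Jacobian of the log transform
    lp <- lp + sum(dnorm(exp(logd), 0, priorSd, log = TRUE) + log(2) + logd)
  }
  lp + sum(dnorm(phi[-seq_len(nTheta)], 0, priorSd, log = TRUE))
}

.logPosterior <- function(phi, nTheta, x, y, priorSd, priorOnly) {
  lp <- .logPrior(phi, nTheta, priorSd)
  if (!priorOnly) {
    p <- .phiToParams(phi, nTheta)
    lp <- lp + .clmLoglik(p$theta, p$beta, x, y)
  }
  lp
}

## Data-driven initial phi: cut-offs at the logit of the empirical
## cumulative class frequencies, slope 0. Jittered per chain.
.initPhi <- function(y, J, nBeta, jitter) {
  freq <- tabulate(y, nbins = J)
  cum <- cumsum(freq)[-J] / sum(freq)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  theta0 <- qlogis(cum)
  theta0 <- cummax(theta0 + seq_len(J - 1L) * 1e-6)  # enforce strict order
  d <- diff(theta0)
  d[d <= 0] <- 1e-3
  c(theta0[1L], log(d), rep(0, nBeta)) + jitter
}

#' Fit the cumulative link model by MCMC
#'
#' Samples the posterior of the cut-offs theta and slope beta under the
#' categorical likelihood of \code{\link{classProbs}} and vague proper
#' priors (see \code{\link{clmControl}}). Deterministic given
#' \code{control$seed}. Convergence is assessed by split-PSRF; a fit with
#' any PSRF above the threshold is returned with a prominent warning and
#' \code{converged = FALSE}.
#'
#' @param vs a \linkS4class{VariantSet}; all records must carry score and
#'   expert class and span at least two classes.
#' @param control sampler settings from \code{\link{clmControl}};
#'   \code{seed} is mandatory.
#' @return A \linkS4class{PosteriorDraws}.
#' @examples
#' vs <- generateFromCLM(CLMParameters(c(-2, -1, 1, 2), 0.25),
#'                       scores = rnorm(400, 0, 8), seed = 7)
#' fit <- fitBayes(vs, clmControl(nChains = 2, nIter = 600, nBurnin = 300,
#'                                seed = 7))
#' summarizePosterior(fit)
#' @export
fitBayes <- function(vs, control = clmControl()) {
  if (is.null(control$seed)) stop("control$seed is mandatory")
  rec <- variantRecords(vs)
  J <- nClasses(vs)
  if (!control$priorOnly) {
    if (anyNA(rec$expert_class) || anyNA(rec$score))
      stop("all records must have expert_class and score; apply fitSubset()")
    if (nrow(rec) < J)
      stop("need at least J records to fit")
    if (length(unique(rec$expert_class)) < 2L)
      stop("degenerate data: all records in one class")
  }
  nTheta <- J - 1L
  nBeta <- 1L
  nPar <- nTheta + nBeta

  if (control$priorOnly) {
    x <- numeric(0); y <- integer(0); m <- 0; s <- 1
  } else {
    m <- mean(rec$score); s <- sd(rec$score)
    if (!is.finite(s) || s == 0) s <- 1
    x <- (rec$score - m) / s
    y <- rec$expert_class
  }

  nKeep <- control$nIter - control$nBurnin
  draws <- array(NA_real_,
                 dim = c(nKeep, nPar, control$nChains),
                 dimnames = list(NULL,
                                 c(paste0("theta", seq_len(nTheta)),
                                   paste0("beta", seq_len(nBeta))),
                                 paste0("chain", seq_len(control$nChains))))
  accRate <- numeric(control$nChains)

  for (ch in seq_len(control$nChains)) {
    set.seed(.substreamSeed(control$seed, paste0("fitBayes-chain", ch)))
    phi <- .initPhi(if (length(y)) y else rep(seq_len(J), 2L), J, nBeta,
                    jitter = rnorm(nPar, 0, 0.1))
    lp <- .logPosterior(phi, nTheta, x, y, control$priorSd, control$priorOnly)
    step <- rep(0.1, nPar)
    nAcc <- 0L; nProp <- 0L
    for (it in seq_len(control$nIter)) {
      for (k in seq_len(nPar)) {
        prop <- phi
        prop[k] <- phi[k] + rnorm(1L, 0, step[k])
        lpProp <- .logPosterior(prop, nTheta, x, y, control$priorSd,
                                control$priorOnly)
        acc <- is.finite(lpProp) && log(runif(1L)) < (lpProp - lp)
        if (acc) { phi <- prop; lp <- lpProp }
        if (it <= control$nBurnin) {
          # Robbins-Monro adaptation toward 0.44 acceptance, burn-in only
          step[k] <- exp(log(step[k]) +
                           ((if (acc) 1 else 0) - 0.44) / sqrt(it))
        } else {
          nProp <- nProp + 1L
          nAcc <- nAcc + (if (acc) 1L else 0L)
        }
      }
      if (it > control$nBurnin) {
        p <- .phiToParams(phi, nTheta)
        # back-transform to the original score scale
        draws[it - control$nBurnin, , ch] <-
          c(p$theta + (m / s) * p$beta[1L], p$beta / s)
      }
    }
    accRate[ch] <- nAcc / max(nProp, 1L)
  }

  out <- new("PosteriorDraws", draws = draws, nClasses = J,
             nBurnin = control$nBurnin, seed = as.integer(control$seed),
             psrf = rep(NA_real_, nPar), converged = NA,
             acceptance = accRate)
  r <- psrf(out)
  out@psrf <- r
  out@converged <- all(r < control$psrfThreshold)
  if (!out@converged)
    warning("MCMC did not converge: max PSRF = ",
            format(max(r), digits = 4),
            " (threshold ", control$psrfThreshold, "). ",
            "Treat downstream results with caution.")
  out
}

#' Split potential scale reduction factor
#'
#' Gelman-Rubin convergence diagnostic per parameter, computed on chains
#' split in half. With \code{rankNormalized = TRUE} (default) draws are
#' replaced by normal scores of their pooled ranks first, making the
#' diagnostic robust to heavy tails. Identical constant chains give exactly
#' 1 with \code{rankNormalized = FALSE}.
#'
#' @param draws a \linkS4class{PosteriorDraws} with >= 2 chains and >= 10
#'   kept iterations.
#' @param rankNormalized logical.
#' @return Named numeric vector of PSRF values, one per parameter.
#' @export
psrf <- function(draws, rankNormalized = TRUE) {
  a <- draws@draws
  d <- dim(a)
  if (d[3L] < 2L) stop("PSRF requires at least 2 chains")
  if (d[1L] < 10L) stop("PSRF requires at least 10 kept iterations")
  half <- d[1L] %/% 2L
  vapply(seq_len(d[2L]), function(p) {
    segs <- list()
    for (ch in seq_len(d[3L])) {
      segs[[length(segs) + 1L]] <- a[seq_len(half), p, ch]
      segs[[length(segs) + 1L]] <- a[half + seq_len(half), p, ch]
    }
    mat <- do.call(cbind, segs)
    if (rankNormalized) {
      r <- rank(as.vector(mat), ties.method = "average")
      z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
      mat <- matrix(z, nrow = nrow(mat))
    }
    nI <- nrow(mat)
    W <- mean(apply(mat, 2L, var))
    B <- nI * var(colMeans(mat))
    if (!is.finite(W) || W == 0) return(1)
    # values below 1 (the (n-1)/n factor with negligible between-chain
    # variance) carry no convergence information: report exactly 1
    max(1, sqrt(((nI - 1) / nI * W + B / nI) / W))
  }, numeric(1), USE.NAMES = FALSE) -> out
  names(out) <- dimnames(a)[[2L]]
  out
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, sd, central 95\% credible interval and
#' split-PSRF, pooling all chains.
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @return data.frame with rows theta1..theta(J-1), beta1..; columns
#'   \code{mean}, \code{sd}, \code{lower}, \code{upper}, \code{psrf}.
#' @export
summarizePosterior <- function(draws) {
  a <- draws@draws
  if (length(a) == 0L) stop("empty draws")
  pooled <- apply(a, 2L, identity)      # (iter*chain) x par
  if (is.null(dim(pooled))) pooled <- matrix(pooled, ncol = dim(a)[2L])
  q <- apply(pooled, 2L, quantile, probs = c(0.025, 0.975), names = FALSE,
             type = 7)
  data.frame(parameter = dimnames(a)[[2L]],
             mean = colMeans(pooled),
             sd = apply(pooled, 2L, sd),
             lower = q[1L, ],
             upper = q[2L, ],
             psrf = draws@psrf,
             row.names = NULL)
}

#' Posterior-mean parameters
#'
#' Convenience accessor: the posterior means of theta and beta as a
#' \linkS4class{CLMParameters} (means of strictly increasing draws are
#' strictly increasing).
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @return A \linkS4class{CLMParameters}.
#' @export
posteriorMeanParameters <- function(draws) {
  s <- summarizePosterior(draws)
  nTheta <- draws@nClasses - 1L
  CLMParameters(theta = s$mean[seq_len(nTheta)],
                beta = s$mean[-seq_len(nTheta)])
}

#' Maximum-likelihood fit of the cumulative link model
#'
#' Direct numerical maximization of \code{\link{logLikelihood}} over the
#' unconstrained parameterization (theta_1, log-increments, beta), serving
#' as a frequentist cross-check of \code{\link{fitBayes}}: with vague
#' priors and n in the thousands the posterior mean and the MLE agree to
#' within Monte-Carlo error.
#'
#' @param vs a \linkS4class{VariantSet} (fit subset).
#' @return A \linkS4class{CLMParameters} with attribute \code{logLik}.
#' @export
fitML <- function(vs) {
  rec <- variantRecords(vs)
  J <- nClasses(vs)
  if (anyNA(rec$expert_class) || anyNA(rec$score))
    stop("all records must have expert_class and score; apply fitSubset()")
  if (length(unique(rec$expert_class)) < 2L)
    stop("degenerate data: all records in one class")
  nTheta <- J - 1L
  m <- mean(rec$score); s <- sd(rec$score)
  if (!is.finite(s) || s == 0) s <- 1
  x <- (rec$score - m) / s
  y <- rec$expert_class
  negll <- function(phi) {
    p <- .phiToParams(phi, nTheta)
    -.clmLoglik(p$theta, p$beta, x, y)
  }
  phi0 <- .initPhi(y, J, 1L, jitter = 0)
  opt <- optim(phi0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  p <- .phiToParams(opt$par, nTheta)
  if (abs(p$beta[1L]) > 30)
    # likelihood is monotone in beta under complete separation: a huge
    # standardized slope (possibly with the iteration cap hit) is the
    # diagnostic, not an optimizer failure
    warning("very large standardized slope (|beta| > 30): ",
            "possible complete separation of classes by score")
  else if (opt$convergence != 0L)
    stop("ML optimizer did not converge (code ", opt$convergence, "): ",
         opt$message)
  params <- CLMParameters(theta = p$theta + (m / s) * p$beta[1L],
                          beta = p$beta / s)
  attr(params, "logLik") <- -opt$value
  params
}
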