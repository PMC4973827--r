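## Posterior-deviance discrepancy flagging and class reassignment.

#' @importFrom stats pt
NULL

#' Posterior mean deviance per variant
#'
#' Averages the observation deviance \eqn{-2\log P(Y_i)} over posterior
#' draws (not at a point estimate; a switch exposes the point-estimate
#' alternative for sensitivity analysis). Variants strictly above the
#' empirical 95th percentile (linear-interpolation quantile) of the mean
#' deviance are flagged as discrepant: the observations the fitted model
#' finds most surprising. By construction the flagged fraction never
#' exceeds 5\% + 1/n, and when all mean deviances are equal none exceed the
#' threshold strictly, so none are flagged.
#'
#' @param draws a \linkS4class{PosteriorDraws} fitted on \code{vs}.
#' @param vs the \linkS4class{VariantSet} the model was fitted on.
#' @param percentile flagging percentile (default 0.95).
#' @param pointEstimate if TRUE, evaluate deviance at the posterior-mean
#'   parameters instead of averaging over draws.
#' @param thin keep every \code{thin}-th draw when averaging (default 1 =
#'   all draws).
#' @return A \linkS4class{DevianceProfile}.
#' @export
meanDeviances <- function(draws, vs, percentile = 0.95,
                          pointEstimate = FALSE, thin = 1L) {
  rec <- variantRecords(vs)
  if (anyNA(rec$expert_class) || anyNA(rec$score))
    stop("all records must have expert_class and score")
  J <- draws@nClasses
  nTheta <- J - 1L
  y <- rec$expert_class
  x <- rec$score
  ext <- function(theta) c(-Inf, theta, Inf)

  if (pointEstimate) {
    p <- posteriorMeanParameters(draws)
    e <- ext(p@theta); eta <- x * p@beta[1L]
    md <- -2 * .logSigmoidDiff(e[y + 1L] - eta, e[y] - eta)
  } else {
    a <- draws@draws
    keep <- seq(1L, dim(a)[1L], by = as.integer(thin))
    total <- numeric(nrow(rec))
    nInf <- 0L; nDraws <- 0L
    for (ch in seq_len(dim(a)[3L])) {
      for (it in keep) {
        theta <- a[it, seq_len(nTheta), ch]
        beta <- a[it, nTheta + 1L, ch]
        e <- ext(theta); eta <- x * beta
        dev <- -2 * .logSigmoidDiff(e[y + 1L] - eta, e[y] - eta)
        nInf <- nInf + sum(is.infinite(dev))
        total <- total + dev
        nDraws <- nDraws + 1L
      }
    }
    md <- total / nDraws
    if (nInf > 0.01 * nDraws * nrow(rec))
      warning("infinite deviance in more than 1% of draw-record pairs; ",
              "possible model misfit")
  }
  threshold <- as.numeric(quantile(md[is.finite(md)], probs = percentile,
                                   type = 7, names = FALSE))
  # Inf mean deviance is always flagged
  profile <- data.frame(variant_id = rec$variant_id,
                        mean_deviance = md,
                        flagged = md > threshold,
                        stringsAsFactors = FALSE)
  new("DevianceProfile", profile = profile, threshold = threshold,
      percentile = percentile)
}

#' Reassign flagged variants to the model-preferred class
#'
#' Unflagged variants keep their expert class and land on the diagonal of
#' the model-vs-expert matrix; flagged variants are assigned
#' \code{\link{assignClass}} at the posterior-mean parameters (or at
#' posterior-averaged class probabilities with
#' \code{useMeanParams = FALSE}). A flagged variant whose model-preferred
#' class equals its expert class stays on the diagonal and does not count
#' as discordant, so the number of discordant variants is at most the
#' number flagged. Column sums of the matrix always reproduce the per-class
#' counts of the data. False positives are expert class 1 assigned to
#' class J; false negatives expert class J assigned to class 1.
#'
#' @param profile a \linkS4class{DevianceProfile} from
#'   \code{\link{meanDeviances}}.
#' @param draws the \linkS4class{PosteriorDraws} behind \code{profile}.
#' @param vs the fitted \linkS4class{VariantSet}.
#' @param useMeanParams argmax at posterior-mean parameters (default) or at
#'   draw-averaged class probabilities.
#' @return A \linkS4class{ReassignmentReport}.
#' @export
reassign <- function(profile, draws, vs, useMeanParams = TRUE) {
  rec <- variantRecords(vs)
  prof <- profile@profile
  if (!identical(prof$variant_id, rec$variant_id))
    stop("profile and variant set do not match")
  J <- nClasses(vs)
  nTheta <- J - 1L
  model_class <- rec$expert_class
  flaggedIdx <- which(prof$flagged)
  if (length(flaggedIdx)) {
    xs <- rec$score[flaggedIdx]
    if (useMeanParams) {
      p <- posteriorMeanParameters(draws)
      logp <- .logClassProbMatrix(p@theta, p@beta, xs)
      model_class[flaggedIdx] <- max.col(logp, ties.method = "first")
    } else {
      a <- draws@draws
      acc <- matrix(0, length(xs), J)
      for (ch in seq_len(dim(a)[3L]))
        for (it in seq_len(dim(a)[1L]))
          acc <- acc + exp(.logClassProbMatrix(a[it, seq_len(nTheta), ch],
                                               a[it, nTheta + 1L, ch], xs))
      model_class[flaggedIdx] <- max.col(acc, ties.method = "first")
    }
  }
  mat <- table(factor(model_class, levels = seq_len(J)),
               factor(rec$expert_class, levels = seq_len(J)))
  mat <- matrix(as.integer(mat), J, J,
                dimnames = list(model = paste0("class", seq_len(J)),
                                expert = paste0("class", seq_len(J))))
  asg <- data.frame(variant_id = rec$variant_id,
                    expert_class = rec$expert_class,
                    model_class = as.integer(model_class),
                    flagged = prof$flagged,
                    mean_deviance = prof$mean_deviance,
                    stringsAsFactors = FALSE)
  new("ReassignmentReport",
      matrix = mat,
      assignments = asg,
      falsePositives = rec$variant_id[rec$expert_class == 1L &
                                        model_class == J],
      falseNegatives = rec$variant_id[rec$expert_class == J &
                                        model_class == 1L],
      nDiscordant = as.integer(sum(model_class != rec$expert_class)),
      nFlagged = as.integer(sum(prof$flagged)))
}

#' Spearman rank correlation between expert class and score
#'
#' Midrank-based Spearman correlation (Pearson correlation of midranks,
#' computed from the product-moment formula) with the large-sample
#' t-approximation two-sided p-value.
#'
#' @param vs a \linkS4class{VariantSet} with >= 3 classified, scored
#'   records.
#' @return List with \code{rho}, \code{pValue} and \code{n}.
#' @export
spearmanClassScore <- function(vs) {
  rec <- variantRecords(vs)
  ok <- !is.na(rec$expert_class) & !is.na(rec$score)
  cls <- rec$expert_class[ok]
  score <- rec$score[ok]
  n <- length(cls)
  if (n < 3L) stop("need at least 3 records with class and score")
  rx <- rank(cls, ties.method = "average")
  ry <- rank(score, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0)
    stop("zero variance in class or score: correlation undefined")
  rho <- sum(dx * dy) / sqrt(sx * sy)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, pValue = 2 * pt(-abs(tstat), df = n - 2), n = n)
}
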