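#' @import methods
NULL

.RECORD_COLUMNS <- c("variant_id", "gene", "score", "expert_class",
                     "impact", "effect_label")

#' VariantSet: a validated table of scored variants
#'
#' Container for one analysis set of variants. Each record carries an opaque
#' variant identifier (conventionally \code{gene:HGVS-cDNA}), a continuous
#' deleteriousness score (PHRED-like scaled score; may be negative), an
#' optional ordinal expert pathogenicity class (IARC five-tier, 1 = not
#' pathogenic ... 5 = pathogenic), and optional qualitative effect annotation
#' (SnpEff-style impact \code{HIGH}/\code{MODERATE}/\code{LOW}/\code{MODIFIER}
#' plus a free-text effect label). Rows dropped during import are accounted
#' for in \code{exclusionLog}, never silently.
#'
#' @slot records data.frame with columns \code{variant_id}, \code{gene},
#'   \code{score}, \code{expert_class}, \code{impact}, \code{effect_label}.
#' @slot nClasses integer, the number of ordinal classes J (default 5).
#' @slot exclusionLog data.frame with columns \code{variant_id},
#'   \code{reason}: one row per input row that was excluded.
#'
#' @exportClass VariantSet
setClass("VariantSet",
         representation(records = "data.frame",
                        nClasses = "integer",
                        exclusionLog = "data.frame"),
         prototype(records = data.frame(variant_id = character(),
                                        gene = character(),
                                        score = numeric(),
                                        expert_class = integer(),
                                        impact = character(),
                                        effect_label = character(),
                                        stringsAsFactors = FALSE),
                   nClasses = 5L,
                   exclusionLog = data.frame(variant_id = character(),
                                             reason = character(),
                                             stringsAsFactors = FALSE)))

setValidity("VariantSet", function(object) {
  rec <- object@records
  msgs <- character()
  if (!all(.RECORD_COLUMNS %in% names(rec)))
    msgs <- c(msgs, paste("records must have columns:",
                          paste(.RECORD_COLUMNS, collapse = ", ")))
  else {
    if (anyDuplicated(rec$variant_id))
      msgs <- c(msgs, "variant_id must be unique within a VariantSet")
    if (any(rec$variant_id == "" | is.na(rec$variant_id)))
      msgs <- c(msgs, "variant_id must be non-empty")
    if (any(!is.finite(rec$score) & !is.na(rec$score)))
      msgs <- c(msgs, "score must be finite where present")
    cls <- rec$expert_class
    bad <- !is.na(cls) & (cls < 1L | cls > object@nClasses |
                            cls != round(cls))
    if (any(bad))
      msgs <- c(msgs, sprintf("expert_class must be an integer in [1, %d]",
                              object@nClasses))
    imp <- rec$impact
    if (any(!is.na(imp) & !(imp %in% .impactLevels)))
      msgs <- c(msgs, "impact must be HIGH, MODERATE, LOW or MODIFIER")
  }
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    msgs <- c(msgs, "nClasses must be a single integer >= 2")
  if (!all(c("variant_id", "reason") %in% names(object@exclusionLog)))
    msgs <- c(msgs, "exclusionLog must have columns variant_id, reason")
  if (length(msgs)) msgs else TRUE
})

#' CLMParameters: cut-offs and regression weights of a cumulative link model
#'
#' The proportional-odds model places J - 1 strictly increasing cut-offs
#' \eqn{\theta_1 < \dots < \theta_{J-1}} on the logit scale and models the
#' cumulative class probabilities as
#' \eqn{logit\, \gamma_{ij} = \theta_j - x_i^\top \beta}.
#' Positive \eqn{\beta} therefore shifts probability mass toward higher
#' (more pathogenic) classes as the score rises.
#'
#' @slot theta numeric vector of J - 1 strictly increasing finite cut-offs.
#' @slot beta numeric vector of regression weights (length 1 for a single
#'   score covariate).
#'
#' @exportClass CLMParameters
setClass("CLMParameters",
         representation(theta = "numeric", beta = "numeric"))

setValidity("CLMParameters", function(object) {
  msgs <- character()
  if (length(object@theta) < 1L || any(!is.finite(object@theta)))
    msgs <- c(msgs, "theta must be non-empty and finite")
  if (length(object@theta) > 1L && any(diff(object@theta) <= 0))
    msgs <- c(msgs, "theta must be strictly increasing")
  if (length(object@beta) < 1L || any(!is.finite(object@beta)))
    msgs <- c(msgs, "beta must be non-empty and finite")
  if (length(msgs)) msgs else TRUE
})

#' PosteriorDraws: MCMC samples of cumulative link model parameters
#'
#' Post-burn-in draws of (theta, beta) across chains, on the original score
#' scale, together with convergence diagnostics. Every stored draw satisfies
#' the theta ordering invariant by construction of the sampler's
#' parameterization.
#'
#' @slot draws numeric array with dim (iterations, parameters, chains);
#'   parameter columns named \code{theta1..theta[J-1]}, \code{beta1..}.
#' @slot nClasses integer J.
#' @slot nBurnin integer, burn-in iterations discarded per chain.
#' @slot seed integer, global seed that produced the draws.
#' @slot psrf numeric, split potential scale reduction factor per parameter.
#' @slot converged logical, TRUE when all PSRF values fell below the
#'   configured threshold.
#' @slot acceptance numeric, per-chain mean Metropolis acceptance rate.
#'
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
         representation(draws = "array",
                        nClasses = "integer",
                        nBurnin = "integer",
                        seed = "integer",
                        psrf = "numeric",
                        converged = "logical",
                        acceptance = "numeric"))

setValidity("PosteriorDraws", function(object) {
  d <- dim(object@draws)
  msgs <- character()
  if (length(d) != 3L)
    msgs <- c(msgs, "draws must be a 3-d array (iteration, parameter, chain)")
  else {
    nTheta <- object@nClasses - 1L
    if (d[2L] < nTheta + 1L)
      msgs <- c(msgs, "draws must hold J-1 thetas plus at least one beta")
  }
  if (length(msgs)) msgs else TRUE
})

#' DevianceProfile: posterior mean deviance and discrepancy flags
#'
#' Per-variant posterior mean of the observation deviance
#' \eqn{-2 \log P(Y_i)} and a flag for the variants the fitted model finds
#' surprising: those strictly above the empirical 95th percentile of the
#' mean deviance.
#'
#' @slot profile data.frame with columns \code{variant_id},
#'   \code{mean_deviance}, \code{flagged}.
#' @slot threshold numeric, the percentile cut actually used.
#' @slot percentile numeric, the percentile level (default 0.95).
#'
#' @exportClass DevianceProfile
setClass("DevianceProfile",
         representation(profile = "data.frame",
                        threshold = "numeric",
                        percentile = "numeric"))

setValidity("DevianceProfile", function(object) {
  p <- object@profile
  msgs <- character()
  need <- c("variant_id", "mean_deviance", "flagged")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, "profile must have variant_id, mean_deviance, flagged")
  else if (!all(p$flagged == (p$mean_deviance > object@threshold)))
    msgs <- c(msgs, "flagged must equal (mean_deviance > threshold)")
  if (length(msgs)) msgs else TRUE
})

#' ReassignmentReport: observed-vs-model class matrix
#'
#' Cross-tabulation of model-assigned class (rows) against expert class
#' (columns). Unflagged variants keep their expert class and contribute only
#' to the diagonal; flagged variants are assigned the model-preferred class
#' at the posterior-mean parameters. False positives are expert class 1
#' reassigned to class J; false negatives expert class J reassigned to
#' class 1.
#'
#' @slot matrix J x J integer matrix, rows = model class, cols = expert class.
#' @slot assignments data.frame with per-variant \code{variant_id},
#'   \code{expert_class}, \code{model_class}, \code{flagged},
#'   \code{mean_deviance}.
#' @slot falsePositives character, variant_ids in cell (J, 1).
#' @slot falseNegatives character, variant_ids in cell (1, J).
#' @slot nDiscordant integer, sum of off-diagonal cells.
#' @slot nFlagged integer, number of flagged variants (>= nDiscordant).
#'
#' @exportClass ReassignmentReport
setClass("ReassignmentReport",
         representation(matrix = "matrix",
                        assignments = "data.frame",
                        falsePositives = "character",
                        falseNegatives = "character",
                        nDiscordant = "integer",
                        nFlagged = "integer"))

setValidity("ReassignmentReport", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  off <- sum(m) - sum(diag(m))
  if (off != object@nDiscordant)
    msgs <- c(msgs, "nDiscordant must equal the off-diagonal sum")
  if (length(msgs)) msgs else TRUE
})

#' PriorityList: class-3 variants ranked by extreme-class probability
#'
#' Variants of uncertain significance (expert class 3) whose model
#' probability of the extreme class (pathogenic J or benign 1) reaches a
#' threshold, sorted by that probability then score, descending. The implied
#' score cutoff is the smallest score at which the threshold is reached
#' under the fitted monotone model.
#'
#' @slot entries data.frame with \code{variant_id}, \code{gene},
#'   \code{score}, \code{p_class1}, \code{p_class5} (named \code{p_classJ}
#'   for general J), \code{p_target}.
#' @slot thresholdProbability numeric in (0.5, 1).
#' @slot impliedScoreCutoff numeric, smallest score with target probability
#'   >= threshold (NA when the fitted slope is not positive).
#' @slot direction character, \code{"pathogenic"} or \code{"benign"}.
#'
#' @exportClass PriorityList
setClass("PriorityList",
         representation(entries = "data.frame",
                        thresholdProbability = "numeric",
                        impliedScoreCutoff = "numeric",
                        direction = "character"))

#' OverrideResult: second-tier impact-annotation override
#'
#' Result of overriding model-predicted benign calls (model class at or
#' below a cutoff) for variants carrying a HIGH qualitative impact
#' annotation, rescuing e.g. structural/truncating variants whose scaled
#' score collapsed.
#'
#' @slot table data.frame with \code{variant_id}, \code{model_class},
#'   \code{impact}, \code{overridden}, \code{final_class}.
#' @slot nCandidates integer, variants with model class <= cutoff.
#' @slot nOverridden integer, candidates with impact HIGH.
#' @slot nMissingImpact integer, candidates lacking any impact annotation.
#' @slot lowClassCutoff integer trigger bound (default 2).
#' @slot overrideClass integer class assigned on override (default J).
#'
#' @exportClass OverrideResult
setClass("OverrideResult",
         representation(table = "data.frame",
                        nCandidates = "integer",
                        nOverridden = "integer",
                        nMissingImpact = "integer",
                        lowClassCutoff = "integer",
                        overrideClass = "integer"))

setValidity("OverrideResult", function(object) {
  tb <- object@table
  msgs <- character()
  bad <- tb$overridden &
    !(tb$impact %in% "HIGH" & tb$model_class <= object@lowClassCutoff)
  if (any(bad))
    msgs <- c(msgs, "overridden implies impact HIGH and low model class")
  expect <- ifelse(tb$overridden, object@overrideClass, tb$model_class)
  if (!all(tb$final_class == expect))
    msgs <- c(msgs, "final_class inconsistent with override rule")
  if (length(msgs)) msgs else TRUE
})
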