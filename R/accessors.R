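## Constructors, accessors and show methods.

#' Construct a VariantSet
#'
#' @param records data.frame of variant records; missing columns among
#'   \code{gene}, \code{expert_class}, \code{impact}, \code{effect_label}
#'   are added as all-missing.
#' @param nClasses number of ordinal classes J.
#' @param exclusionLog data.frame of (variant_id, reason) for dropped rows.
#' @return A \linkS4class{VariantSet}.
#' @examples
#' vs <- VariantSet(data.frame(variant_id = c("MLH1:c.1A>G", "MSH2:c.2C>T"),
#'                             score = c(25.1, 3.2),
#'                             expert_class = c(5L, 1L)))
#' nVariants(vs)
#' @export
VariantSet <- function(records,
                       nClasses = 5L,
                       exclusionLog = NULL) {
  stopifnot(is.data.frame(records))
  if (!"variant_id" %in% names(records))
    stop("records must have a variant_id column")
  if (!"score" %in% names(records))
    stop("records must have a score column")
  if (!"gene" %in% names(records))
    records$gene <- vapply(strsplit(as.character(records$variant_id), ":",
                                    fixed = TRUE),
                           `[`, character(1), 1L)
  n <- nrow(records)
  if (!"expert_class" %in% names(records))
    records$expert_class <- rep(NA_integer_, n)
  if (!"impact" %in% names(records))
    records$impact <- rep(NA_character_, n)
  if (!"effect_label" %in% names(records))
    records$effect_label <- rep(NA_character_, n)
  records$variant_id <- as.character(records$variant_id)
  records$gene <- as.character(records$gene)
  records$score <- as.numeric(records$score)
  records$expert_class <- as.integer(records$expert_class)
  records$impact <- as.character(records$impact)
  records$effect_label <- as.character(records$effect_label)
  records <- records[, .RECORD_COLUMNS, drop = FALSE]
  rownames(records) <- NULL
  if (is.null(exclusionLog))
    exclusionLog <- data.frame(variant_id = character(),
                               reason = character(),
                               stringsAsFactors = FALSE)
  new("VariantSet", records = records, nClasses = as.integer(nClasses),
      exclusionLog = exclusionLog)
}

#' Construct CLMParameters
#'
#' @param theta strictly increasing numeric vector of J - 1 cut-offs.
#' @param beta numeric regression weight(s).
#' @return A \linkS4class{CLMParameters}.
#' @examples
#' CLMParameters(theta = c(-2, -1, 1, 2), beta = 0.25)
#' @export
CLMParameters <- function(theta, beta) {
  new("CLMParameters", theta = as.numeric(theta), beta = as.numeric(beta))
}

#' @describeIn VariantSet Number of retained variant records.
#' @param x,object a VariantSet.
#' @export
nVariants <- function(x) nrow(x@records)

#' @describeIn VariantSet The record table.
#' @export
variantRecords <- function(x) x@records

#' @describeIn VariantSet The exclusion log.
#' @export
exclusionLog <- function(x) x@exclusionLog

#' @describeIn VariantSet Number of ordinal classes J.
#' @export
nClasses <- function(x) x@nClasses

#' Cut-offs of a CLMParameters object
#' @param x a CLMParameters.
#' @export
thetaCutoffs <- function(x) x@theta

#' Regression weights of a CLMParameters object
#' @param x a CLMParameters.
#' @export
betaWeights <- function(x) x@beta

#' @describeIn reassign Per-variant assignment table of a ReassignmentReport.
#' @param x a ReassignmentReport.
#' @export
assignments <- function(x) x@assignments

#' @describeIn reassign Model-vs-expert class matrix.
#' @export
reassignmentMatrix <- function(x) x@matrix

#' @describeIn reassign Expert-class-1 variants reassigned to class J.
#' @export
falsePositives <- function(x) x@falsePositives

#' @describeIn reassign Expert-class-J variants reassigned to class 1.
#' @export
falseNegatives <- function(x) x@falseNegatives

setMethod("show", "VariantSet", function(object) {
  rec <- object@records
  cat(sprintf("VariantSet with %d records (J = %d classes), %d excluded\n",
              nrow(rec), object@nClasses, nrow(object@exclusionLog)))
  if (nrow(rec)) {
    tab <- table(factor(rec$expert_class, levels = seq_len(object@nClasses)),
                 useNA = "ifany")
    cat("  per-class counts:", paste(tab, collapse = " / "), "\n")
    cat(sprintf("  score range: [%.2f, %.2f]\n",
                min(rec$score, na.rm = TRUE), max(rec$score, na.rm = TRUE)))
  }
  invisible(NULL)
})

setMethod("show", "CLMParameters", function(object) {
  cat("CLMParameters (logit gamma_j = theta_j - x'beta)\n")
  cat("  theta:", paste(sprintf("%.4f", object@theta), collapse = ", "), "\n")
  cat("  beta: ", paste(sprintf("%.4f", object@beta), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PosteriorDraws", function(object) {
  d <- dim(object@draws)
  cat(sprintf(
    "PosteriorDraws: %d chains x %d post-burn-in iterations, %d parameters\n",
    d[3L], d[1L], d[2L]))
  cat(sprintf("  burn-in %d, seed %d, converged: %s (max PSRF %.4f)\n",
              object@nBurnin, object@seed, object@converged,
              max(object@psrf)))
  invisible(NULL)
})

setMethod("show", "DevianceProfile", function(object) {
  cat(sprintf(
    "DevianceProfile: %d variants, %d flagged above the %.0fth percentile (threshold %.3f)\n",
    nrow(object@profile), sum(object@profile$flagged),
    100 * object@percentile, object@threshold))
  invisible(NULL)
})

setMethod("show", "ReassignmentReport", function(object) {
  cat(sprintf(
    "ReassignmentReport: %d flagged, %d discordant, %d false positives, %d false negatives\n",
    object@nFlagged, object@nDiscordant, length(object@falsePositives),
    length(object@falseNegatives)))
  print(object@matrix)
  invisible(NULL)
})

setMethod("show", "PriorityList", function(object) {
  cat(sprintf(
    "PriorityList (%s): %d class-3 variants with P >= %.3f; implied score cutoff %.2f\n",
    object@direction, nrow(object@entries), object@thresholdProbability,
    object@impliedScoreCutoff))
  invisible(NULL)
})

setMethod("show", "OverrideResult", function(object) {
  cat(sprintf(
    "OverrideResult: %d low-class candidates, %d overridden (HIGH impact), %d without impact annotation\n",
    object@nCandidates, object@nOverridden, object@nMissingImpact))
  invisible(NULL)
})
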