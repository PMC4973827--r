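## Prioritization of variants of uncertain significance (expert class 3) and
## the rank-based score-informativeness statistic.

#' Prioritize variants of uncertain significance
#'
#' Selects class-3 variants whose model probability of the extreme class --
#' class J for \code{direction = "pathogenic"}, class 1 for
#' \code{"benign"} -- at the posterior-mean parameters reaches
#' \code{threshold}. Because the fitted slope is positive, that probability
#' is monotone in the score, so the threshold has an equivalent score
#' cutoff, which is derived from the fit (closed form on the logit scale)
#' and reported rather than hard-coded.
#'
#' @param vs the fitted \linkS4class{VariantSet}.
#' @param draws the \linkS4class{PosteriorDraws} of the fit.
#' @param threshold probability threshold in (0.5, 1); default 0.99.
#' @param direction \code{"pathogenic"} (default) or \code{"benign"}.
#' @param useMeanParams probabilities at posterior-mean parameters
#'   (default) or averaged over draws.
#' @param vusClass the expert class treated as "uncertain" (default 3).
#' @return A \linkS4class{PriorityList}, sorted by target probability then
#'   score, descending.
#' @export
prioritizeVUS <- function(vs, draws, threshold = 0.99,
                          direction = c("pathogenic", "benign"),
                          useMeanParams = TRUE, vusClass = 3L) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0.5, threshold < 1)
  rec <- variantRecords(vs)
  J <- nClasses(vs)
  params <- posteriorMeanParameters(draws)
  vus <- rec[!is.na(rec$expert_class) & rec$expert_class == vusClass, ,
             drop = FALSE]
  if (nrow(vus) == 0L) {
    warning("no class-", vusClass, " records to prioritize")
    probs <- matrix(numeric(0), 0L, J)
  } else if (useMeanParams) {
    probs <- exp(.logClassProbMatrix(params@theta, params@beta, vus$score))
  } else {
    a <- draws@draws
    nTheta <- J - 1L
    probs <- matrix(0, nrow(vus), J)
    for (ch in seq_len(dim(a)[3L]))
      for (it in seq_len(dim(a)[1L]))
        probs <- probs + exp(.logClassProbMatrix(a[it, seq_len(nTheta), ch],
                                                 a[it, nTheta + 1L, ch],
                                                 vus$score))
    probs <- probs / (dim(a)[1L] * dim(a)[3L])
  }
  target <- if (direction == "pathogenic") probs[, J] else probs[, 1L]
  entries <- data.frame(variant_id = vus$variant_id,
                        gene = vus$gene,
                        score = vus$score,
                        stringsAsFactors = FALSE)
  for (j in seq_len(J)) entries[[paste0("p_class", j)]] <-
    if (nrow(vus)) probs[, j] else numeric(0)
  entries$p_target <- target
  sel <- entries[target >= threshold, , drop = FALSE]
  sel <- sel[order(-sel$p_target, -sel$score), , drop = FALSE]
  rownames(sel) <- NULL

  # implied score cutoff: P(class J) = sigma(x beta - theta_{J-1}) >= t
  # <=> x >= (theta_{J-1} + logit(t)) / beta  (beta > 0); mirrored for benign
  beta <- params@beta[1L]
  cutoff <- NA_real_
  if (direction == "pathogenic" && beta > 0)
    cutoff <- (params@theta[J - 1L] + qlogis(threshold)) / beta
  if (direction == "benign" && beta > 0)
    cutoff <- (params@theta[1L] - qlogis(threshold)) / beta
  new("PriorityList", entries = sel,
      thresholdProbability = threshold,
      impliedScoreCutoff = cutoff,
      direction = direction)
}

#' Overlap between a priority list and an external candidate list
#'
#' Set intersection and model-only difference, order-stable by the target
#' probability of the priority list. Duplicate identifiers in either input
#' are de-duplicated with a warning.
#'
#' @param pl a \linkS4class{PriorityList}.
#' @param externalIds character vector of variant identifiers, normalized
#'   to the same \code{gene:HGVS} form as the variant table.
#' @return List with \code{intersection} and \code{uniqueToModel}
#'   character vectors.
#' @export
overlapWithList <- function(pl, externalIds) {
  ids <- pl@entries$variant_id
  if (anyDuplicated(ids)) {
    warning("duplicate ids in priority list de-duplicated")
    ids <- ids[!duplicated(ids)]
  }
  externalIds <- as.character(externalIds)
  if (anyDuplicated(externalIds)) {
    warning("duplicate ids in external list de-duplicated")
    externalIds <- externalIds[!duplicated(externalIds)]
  }
  list(intersection = ids[ids %in% externalIds],
       uniqueToModel = ids[!ids %in% externalIds])
}

#' Rank-based AUC of a score separating two groups
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counting one half: the Mann-Whitney U statistic
#' divided by n+ * n-. Used as a per-gene informativeness statistic for a
#' deleteriousness score.
#'
#' @param scoresPos scores of the positive (e.g. pathogenic) group.
#' @param scoresNeg scores of the negative (e.g. population) group.
#' @return AUC in [0, 1].
#' @examples
#' scoreAUC(c(3, 4, 5), c(1, 2, 3))
#' @export
scoreAUC <- function(scoresPos, scoresNeg) {
  scoresPos <- as.numeric(scoresPos); scoresNeg <- as.numeric(scoresNeg)
  if (length(scoresPos) == 0L || length(scoresNeg) == 0L)
    stop("both groups must be non-empty")
  if (anyNA(scoresPos) || anyNA(scoresNeg)) stop("scores must be non-missing")
  r <- rank(c(scoresPos, scoresNeg), ties.method = "average")
  nPos <- length(scoresPos); nNeg <- length(scoresNeg)
  u <- sum(r[seq_len(nPos)]) - nPos * (nPos + 1) / 2
  u / (nPos * nNeg)
}

#' Per-group AUC driver over a labelled score table
#'
#' Applies \code{\link{scoreAUC}} within each group (typically gene) of a
#' user-supplied table of scores with binary labels.
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1: TRUE/1 = positive.
#' @param groups grouping factor (e.g. gene symbol).
#' @return data.frame with \code{group}, \code{nPos}, \code{nNeg},
#'   \code{auc} (NA when a group lacks one of the labels).
#' @export
groupedScoreAUC <- function(scores, labels, groups) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels),
            length(scores) == length(groups))
  out <- lapply(split(seq_along(scores), groups), function(idx) {
    pos <- scores[idx][labels[idx]]
    neg <- scores[idx][!labels[idx]]
    data.frame(nPos = length(pos), nNeg = length(neg),
               auc = if (length(pos) && length(neg))
                 scoreAUC(pos, neg) else NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
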