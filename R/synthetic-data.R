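## Synthetic-data generators.
##
## Three generators cover the statistical structure the analysis assumes:
## (a) a Gaussian per-class emulator of an expert-curated mismatch-repair
## variant set (per-class counts, score means and SDs of the curated
## snapshot are the defaults), (b) an exact generative sampler from the
## cumulative link model for parameter-recovery experiments, and (c) a
## fixture of structural variants whose scaled score collapsed, for
## exercising the second-tier override. One global seed drives each
## generator through a named substream, so modules are independently yet
## reproducibly testable.

.SYN_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' Emulation spec for the curated variant-set structure
#'
#' Defaults are the per-class counts (151, 84, 751, 181, 1043) and scaled
#' score means / standard deviations (8.41/7.46, 11.44/7.72, 16.87/9.40,
#' 21.41/6.13, 29.04/10.28) of the expert-classified mismatch-repair
#' snapshot the pipeline is calibrated against; together they define a
#' 2,210-variant study-scale dataset.
#'
#' @param classCounts integer vector of per-class record counts.
#' @param classMeans numeric per-class score means.
#' @param classSds positive per-class score standard deviations.
#' @return A validated list of class \code{"EmulationSpec"}.
#' @export
emulationSpec <- function(classCounts = c(151L, 84L, 751L, 181L, 1043L),
                          classMeans = c(8.41, 11.44, 16.87, 21.41, 29.04),
                          classSds = c(7.46, 7.72, 9.40, 6.13, 10.28)) {
  stopifnot(length(classCounts) == length(classMeans),
            length(classCounts) == length(classSds),
            all(classCounts >= 0), all(classSds > 0))
  structure(list(classCounts = as.integer(classCounts),
                 classMeans = as.numeric(classMeans),
                 classSds = as.numeric(classSds)),
            class = "EmulationSpec")
}

#' Emulate the curated variant set
#'
#' For each class j, draws \code{classCounts[j]} scores from
#' Normal(\code{classMeans[j]}, \code{classSds[j]}). Gaussian per-class
#' emulation is an approximation: the real per-class distributions are
#' skewed and the uncertain class is much flatter, so checks built on this
#' emulator are tolerance-based, not exact. Scores are not truncated;
#' negative values are legal.
#'
#' @param spec an \code{\link{emulationSpec}}.
#' @param seed integer global seed (substream \code{"emulate"}).
#' @return A \linkS4class{VariantSet} with synthetic ids
#'   (\code{SYN:gene:c.N}) and no impact annotations.
#' @examples
#' vs <- emulateInsight(seed = 1)
#' table(variantRecords(vs)$expert_class)
#' @export
emulateInsight <- function(spec = emulationSpec(), seed) {
  stopifnot(inherits(spec, "EmulationSpec"), !missing(seed))
  set.seed(.substreamSeed(seed, "emulate"))
  J <- length(spec$classCounts)
  cls <- rep(seq_len(J), spec$classCounts)
  score <- unlist(lapply(seq_len(J), function(j)
    rnorm(spec$classCounts[j], spec$classMeans[j], spec$classSds[j])))
  n <- length(cls)
  gene <- .SYN_GENES[(seq_len(n) - 1L) %% length(.SYN_GENES) + 1L]
  records <- data.frame(
    variant_id = sprintf("SYN:%s:c.%d", gene, seq_len(n)),
    gene = gene,
    score = score,
    expert_class = cls,
    impact = NA_character_,
    effect_label = NA_character_,
    stringsAsFactors = FALSE)
  VariantSet(records, nClasses = J)
}

#' Sample ordinal responses exactly from the cumulative link model
#'
#' For each score, draws a class from \code{\link{classProbs}} at the given
#' parameters: the generative counterpart of the fitted likelihood, used
#' for parameter-recovery experiments where the truth is known by
#' construction.
#'
#' @param params a \linkS4class{CLMParameters}.
#' @param scores numeric vector of covariate values.
#' @param seed integer global seed (substream \code{"fromCLM"}).
#' @return A \linkS4class{VariantSet} with ids \code{SIM:c.N}.
#' @export
generateFromCLM <- function(params, scores, seed) {
  stopifnot(is(params, "CLMParameters"), !missing(seed))
  set.seed(.substreamSeed(seed, "fromCLM"))
  scores <- as.numeric(scores)
  J <- length(params@theta) + 1L
  probs <- exp(.logClassProbMatrix(params@theta, params@beta, scores))
  u <- runif(length(scores))
  cum <- t(apply(probs, 1L, cumsum))
  cls <- 1L + rowSums(u > cum[, -J, drop = FALSE])
  records <- data.frame(
    variant_id = sprintf("SIM:c.%d", seq_along(scores)),
    gene = "SIM",
    score = scores,
    expert_class = as.integer(cls),
    impact = NA_character_,
    effect_label = NA_character_,
    stringsAsFactors = FALSE)
  VariantSet(records, nClasses = J)
}

#' Fixture of structural variants with collapsed scaled scores
#'
#' Emulates the pathology where rank-based scaling inverts extremely high
#' raw scores of structural variants into very low scaled ones: records are
#' expert class 5 (pathogenic) with scores drawn from the lowest 5% tail
#' of the benign-class score distribution (Normal(8.41, 7.46) truncated
#' above at its 5th percentile), so they sit at the very bottom of the
#' score range, safely inside the region where a model fitted to the
#' emulated study prefers class 1.
#' Effect labels are \code{EXON_DELETED} / \code{STOP_GAINED} /
#' \code{FRAME_SHIFT} and impact is \code{HIGH}, so a fitted model calls
#' them benign and \code{\link{applyOverride}} rescues them.
#'
#' @param n number of fixture records (>= 1).
#' @param seed integer global seed (substream \code{"structural"}).
#' @return A \linkS4class{VariantSet} of n class-5, HIGH-impact records.
#' @export
makeStructuralFixture <- function(n, seed) {
  if (missing(n) || n < 1L) stop("n must be >= 1")
  stopifnot(!missing(seed))
  set.seed(.substreamSeed(seed, "structural"))
  n <- as.integer(n)
  # lowest 5% tail of the benign-class score distribution, by inverse CDF
  score <- qnorm(runif(n, 0, 0.05), 8.41, 7.46)
  effect <- sample(c("EXON_DELETED", "STOP_GAINED", "FRAME_SHIFT"), n,
                   replace = TRUE, prob = c(0.7, 0.2, 0.1))
  gene <- .SYN_GENES[(seq_len(n) - 1L) %% length(.SYN_GENES) + 1L]
  records <- data.frame(
    variant_id = sprintf("SV:%s:c.%d", gene, seq_len(n)),
    gene = gene,
    score = score,
    expert_class = 5L,
    impact = "HIGH",
    effect_label = effect,
    stringsAsFactors = FALSE)
  VariantSet(records, nClasses = 5L)
}

#' Concatenate variant sets
#'
#' Row-binds the records (and exclusion logs) of two variant sets with the
#' same number of classes; identifiers must stay unique.
#'
#' @param x,y \linkS4class{VariantSet}s.
#' @return A combined \linkS4class{VariantSet}.
#' @export
bindVariantSets <- function(x, y) {
  stopifnot(nClasses(x) == nClasses(y))
  VariantSet(rbind(variantRecords(x), variantRecords(y)),
             nClasses = nClasses(x),
             exclusionLog = rbind(exclusionLog(x), exclusionLog(y)))
}
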