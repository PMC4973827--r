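## Second-tier impact-annotation override.
##
## Scaled deleteriousness scores collapse for some large structural variants
## (rank-based scaling inverts extremely high raw scores into very low
## scaled ones), so a qualitative annotation impact acts as a second-tier
## test: a model-predicted benign call carrying a HIGH impact annotation
## (EXON_DELETED, STOP_GAINED, FRAME_SHIFT, ...) is overridden to the
## pathogenic class. Impact is consumed as data produced by a standard
## annotator, never computed here.

#' Apply the HIGH-impact override to model-predicted benign calls
#'
#' Every variant whose model-assigned class is at most
#' \code{lowClassCutoff} and whose annotation impact is \code{HIGH} is
#' overridden to \code{overrideClass}. Variants lacking an impact
#' annotation are left untouched and counted separately. The override
#' never demotes and is idempotent.
#'
#' @param report a \linkS4class{ReassignmentReport} (its per-variant model
#'   classes are the input calls).
#' @param vs the \linkS4class{VariantSet} carrying impact annotations.
#' @param lowClassCutoff model classes \code{<=} this value are override
#'   candidates (default 2: predicted benign/likely benign).
#' @param overrideClass class assigned on override (default 5: pathogenic).
#' @return An \linkS4class{OverrideResult}.
#' @export
applyOverride <- function(report, vs, lowClassCutoff = 2L,
                          overrideClass = 5L) {
  asg <- assignments(report)
  rec <- variantRecords(vs)
  idx <- match(asg$variant_id, rec$variant_id)
  if (anyNA(idx)) stop("report and variant set do not match")
  impact <- rec$impact[idx]
  lowClassCutoff <- as.integer(lowClassCutoff)
  overrideClass <- as.integer(overrideClass)
  if (overrideClass < lowClassCutoff)
    stop("overrideClass must not demote below the candidate cutoff")
  candidate <- asg$model_class <= lowClassCutoff
  overridden <- candidate & !is.na(impact) & impact == "HIGH"
  final <- ifelse(overridden, overrideClass, asg$model_class)
  tb <- data.frame(variant_id = asg$variant_id,
                   expert_class = asg$expert_class,
                   model_class = asg$model_class,
                   impact = impact,
                   overridden = overridden,
                   final_class = as.integer(final),
                   stringsAsFactors = FALSE)
  new("OverrideResult", table = tb,
      nCandidates = as.integer(sum(candidate)),
      nOverridden = as.integer(sum(overridden)),
      nMissingImpact = as.integer(sum(candidate & is.na(impact))),
      lowClassCutoff = lowClassCutoff,
      overrideClass = overrideClass)
}
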