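## End-to-end pipeline driver and reporting.

#' @importFrom utils packageVersion
NULL

#' Per-class score summary
#'
#' Per-class n, mean, sd, min and max of the score, plus the overall mean;
#' invariant to record order. The sd of a single-record class is reported
#' as missing.
#'
#' @param vs a non-empty \linkS4class{VariantSet}.
#' @return data.frame with one row per class plus an \code{overall} row.
#' @export
summarizeClasses <- function(vs) {
  rec <- variantRecords(vs)
  if (nrow(rec) == 0L) stop("empty variant set")
  cls <- factor(rec$expert_class, levels = seq_len(nClasses(vs)))
  stat <- function(f) tapply(rec$score, cls, f)
  out <- data.frame(
    class = c(levels(cls), "overall"),
    n = c(as.integer(table(cls)), sum(!is.na(rec$score))),
    mean = c(stat(mean), mean(rec$score)),
    sd = c(stat(sd), sd(rec$score)),
    min = c(stat(min), min(rec$score)),
    max = c(stat(max), max(rec$score)),
    row.names = NULL)
  out
}

.writeReportTsv <- function(df, path, manifestId) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# manifest: ", manifestId), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Run the full calibration pipeline
#'
#' Executes, in order: fit-subset filtering, Bayesian fit, posterior
#' mean-deviance flagging, reassignment, HIGH-impact override and
#' uncertain-variant prioritization, writing a manifest and one report per
#' stage to \code{outdir}. Reruns with identical inputs, settings and seed
#' reproduce identical outputs.
#'
#' @param vs input \linkS4class{VariantSet} (e.g. from
#'   \code{\link{readVariantTable}} or \code{\link{emulateInsight}}).
#' @param outdir output directory, created if needed; NULL skips writing.
#' @param control sampler settings (\code{\link{clmControl}}); the seed is
#'   mandatory and recorded in the manifest.
#' @param priorityThreshold probability threshold for
#'   \code{\link{prioritizeVUS}} (default 0.99).
#' @param percentile deviance flagging percentile (default 0.95).
#' @param lowClassCutoff,overrideClass override rule bounds (default 2, 5).
#' @return Invisibly, a list with elements \code{fitSubset}, \code{draws},
#'   \code{posterior}, \code{profile}, \code{report}, \code{override},
#'   \code{priority}, \code{classSummary}, \code{manifest}.
#' @export
runPipeline <- function(vs, outdir = NULL, control = clmControl(),
                        priorityThreshold = 0.99, percentile = 0.95,
                        lowClassCutoff = 2L, overrideClass = 5L) {
  if (is.null(control$seed)) stop("control$seed is mandatory")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  fs <- stage("fit_subset", fitSubset(vs))
  draws <- stage("fit_bayes", fitBayes(fs, control))
  post <- summarizePosterior(draws)
  profile <- stage("flag", meanDeviances(draws, fs, percentile = percentile))
  report <- stage("reassign", reassign(profile, draws, fs))
  override <- stage("override",
                    applyOverride(report, fs, lowClassCutoff, overrideClass))
  priority <- stage("prioritize",
                    suppressWarnings(
                      prioritizeVUS(fs, draws,
                                    threshold = priorityThreshold)))
  classSummary <- summarizeClasses(fs)

  manifest <- list(
    package = "VariantCLM",
    version = as.character(packageVersion("VariantCLM")),
    seed = control$seed,
    sampler = control[c("nChains", "nIter", "nBurnin", "priorSd",
                        "psrfThreshold")],
    percentile = percentile,
    priorityThreshold = priorityThreshold,
    lowClassCutoff = lowClassCutoff,
    overrideClass = overrideClass,
    nInput = nVariants(vs),
    nFit = nVariants(fs),
    nExcluded = nrow(exclusionLog(fs)),
    nFlagged = report@nFlagged,
    nDiscordant = report@nDiscordant,
    nOverridden = override@nOverridden,
    nPrioritized = nrow(priority@entries),
    converged = draws@converged,
    psrf = as.list(draws@psrf))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifestPath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifestId <- unname(tools::md5sum(manifestPath))
    .writeReportTsv(post, file.path(outdir, "posterior_summary.tsv"),
                    manifestId)
    .writeReportTsv(assignments(report),
                    file.path(outdir, "deviance.tsv"), manifestId)
    .writeReportTsv(override@table, file.path(outdir, "override.tsv"),
                    manifestId)
    .writeReportTsv(priority@entries, file.path(outdir, "priority.tsv"),
                    manifestId)
    .writeReportTsv(classSummary, file.path(outdir, "class_summary.tsv"),
                    manifestId)
    jsonlite::write_json(
      list(manifest = manifestId,
           matrix = unclass(reassignmentMatrix(report)),
           threshold = profile@threshold,
           nFlagged = report@nFlagged,
           nDiscordant = report@nDiscordant,
           falsePositives = falsePositives(report),
           falseNegatives = falseNegatives(report)),
      file.path(outdir, "reassignment.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(fitSubset = fs, draws = draws, posterior = post,
                 profile = profile, report = report, override = override,
                 priority = priority, classSummary = classSummary,
                 manifest = manifest))
}
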