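## Reading, validating and filtering variant tables.
##
## TSV is the canonical interchange format (one row per pre-scored,
## pre-annotated variant); VCF support is read-only convenience. Every input
## row is either retained as a record or logged with an exclusion reason --
## never silently dropped.

#' @importFrom utils read.delim write.table
NULL

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

## TRUE when an allele string contains an IUPAC ambiguity code.
.isAmbiguousAllele <- function(allele) {
  allele <- toupper(as.character(allele))
  out <- rep(FALSE, length(allele))
  ok <- !is.na(allele) & allele != "" & allele != "."
  out[ok] <- vapply(strsplit(allele[ok], ""), function(ch)
    any(ch %in% .IUPAC_AMBIG), logical(1))
  out
}

## Detect an ambiguous substitution embedded in an HGVS-style id such as
## "MLH1:c.1254T>R" (the alt base after ">" is an ambiguity code).
.hgvsAmbiguous <- function(variant_id) {
  grepl(">[RYSWKMBDHVN]$", toupper(as.character(variant_id)))
}

#' Read a variant table from TSV or VCF
#'
#' Reads pre-scored, pre-annotated variants into a
#' \linkS4class{VariantSet}, applying the import exclusion rules: rows with
#' an ambiguous IUPAC allele (e.g. alt \code{R} or \code{Y}, which cannot be
#' scored unambiguously), a missing or unparseable score, an expert class
#' outside 1..J, or a duplicated identifier are excluded and logged with a
#' reason. The number of input rows always equals retained records plus
#' exclusion-log entries.
#'
#' @param path path to the input file.
#' @param format \code{"tsv"} (default; header required, columns
#'   \code{variant_id} and \code{score} mandatory, \code{gene},
#'   \code{expert_class}, \code{impact}, \code{effect_label}, \code{ref},
#'   \code{alt} optional; \code{"."} or empty = missing) or \code{"vcf"}
#'   (VCF 4.x via the VariantAnnotation package).
#' @param nClasses number of ordinal classes J (default 5).
#' @param scoreKey for VCF input, the INFO key carrying the scaled score
#'   (default \code{"CADD_SCALED"}).
#' @param classKey for VCF input, the INFO key carrying the expert class,
#'   if present (default \code{"EXPERT_CLASS"}).
#' @return A \linkS4class{VariantSet}.
#' @seealso \code{\link{fitSubset}}, \code{\link{writeVariantTable}}
#' @export
readVariantTable <- function(path, format = c("tsv", "vcf"), nClasses = 5L,
                             scoreKey = "CADD_SCALED",
                             classKey = "EXPERT_CLASS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- switch(format,
                tsv = .readTsvRaw(path),
                vcf = .readVcfRaw(path, scoreKey, classKey))
  .buildVariantSet(raw, nClasses = as.integer(nClasses))
}

.readTsvRaw <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = TRUE,
                   na.strings = character())
  mandatory <- c("variant_id", "score")
  if (!all(mandatory %in% names(df)))
    stop("TSV is missing mandatory column(s): ",
         paste(setdiff(mandatory, names(df)), collapse = ", "))
  for (col in c("gene", "expert_class", "impact", "effect_label",
                "ref", "alt"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df
}

.readVcfRaw <- function(path, scoreKey, classKey) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  nAlt <- lengths(VariantAnnotation::alt(vcf))
  ids0 <- rownames(vcf)
  if (is.null(ids0)) ids0 <- paste0("var", seq_along(nAlt))
  # decompose multi-allelic records to one row per alt allele; this choice
  # (rather than dropping them) is noted so downstream counts are explicit
  if (any(nAlt > 1L))
    message("decomposed ", sum(nAlt > 1L),
            " multi-allelic VCF record(s) to one row per alt allele")
  vcf <- VariantAnnotation::expand(vcf)
  info <- VariantAnnotation::info(vcf)
  nr <- nrow(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altv <- as.character(VariantAnnotation::alt(vcf))
  # expansion duplicates record names; suffix the substitution to keep ids
  # unique per alt allele
  ids <- paste0(rep(ids0, nAlt), ":", ref, ">", altv)
  score <- if (scoreKey %in% names(info))
    as.character(unlist(info[[scoreKey]])) else
      stop("VCF INFO lacks the score key '", scoreKey, "'")
  cls <- if (classKey %in% names(info))
    as.character(unlist(info[[classKey]])) else NA_character_
  impact <- effect <- rep(NA_character_, nr)
  if ("ANN" %in% names(info)) {
    annList <- info$ANN
    for (i in seq_along(annList)) {
      entries <- as.character(annList[[i]])
      if (length(entries) == 0L) next
      fields <- strsplit(entries, "|", fixed = TRUE)
      impacts <- vapply(fields, function(f)
        if (length(f) >= 3L) f[3L] else NA_character_, character(1))
      best <- .maxImpact(impacts)
      impact[i] <- best
      if (!is.na(best)) {
        k <- which(impacts == best)[1L]
        effect[i] <- fields[[k]][2L]
      }
    }
  }
  data.frame(variant_id = ids,
             gene = NA_character_,
             score = score,
             expert_class = cls,
             impact = impact,
             effect_label = effect,
             ref = ref,
             alt = altv,
             stringsAsFactors = FALSE)
}

## Shared validation/exclusion logic for both input formats.
.buildVariantSet <- function(df, nClasses) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  miss <- function(x) .isMissingToken(x)

  ambig <- .isAmbiguousAllele(df$alt) | .isAmbiguousAllele(df$ref) |
    .hgvsAmbiguous(df$variant_id)
  reason[is.na(reason) & ambig] <- "ambiguous allele"

  noId <- miss(df$variant_id)
  reason[is.na(reason) & noId] <- "missing variant_id"

  score <- suppressWarnings(as.numeric(ifelse(miss(df$score), NA, df$score)))
  reason[is.na(reason) & miss(df$score)] <- "missing score"
  reason[is.na(reason) & !miss(df$score) & is.na(score)] <- "unparseable score"
  reason[is.na(reason) & !is.na(score) & !is.finite(score)] <-
    "non-finite score"

  clsRaw <- ifelse(miss(df$expert_class), NA, df$expert_class)
  clsNum <- suppressWarnings(as.numeric(clsRaw))
  badCls <- !is.na(clsRaw) &
    (is.na(clsNum) | clsNum != round(clsNum) | clsNum < 1 | clsNum > nClasses)
  reason[is.na(reason) & badCls] <- "class out of range"

  dup <- duplicated(df$variant_id) & !miss(df$variant_id)
  reason[is.na(reason) & dup] <- "duplicate variant_id"

  keep <- is.na(reason)
  records <- data.frame(
    variant_id = df$variant_id[keep],
    gene = ifelse(miss(df$gene[keep]),
                  vapply(strsplit(df$variant_id[keep], ":", fixed = TRUE),
                         `[`, character(1), 1L),
                  df$gene[keep]),
    score = score[keep],
    expert_class = as.integer(clsNum[keep]),
    impact = ifelse(miss(df$impact[keep]), NA_character_,
                    toupper(df$impact[keep])),
    effect_label = ifelse(miss(df$effect_label[keep]), NA_character_,
                          df$effect_label[keep]),
    stringsAsFactors = FALSE)
  bad <- !is.na(records$impact) & !(records$impact %in% .impactLevels)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unrecognized impact level set to NA")
    records$impact[bad] <- NA_character_
  }
  excl <- data.frame(variant_id = df$variant_id[!keep],
                     reason = reason[!keep],
                     stringsAsFactors = FALSE)
  stopifnot(nrow(records) + nrow(excl) == n)
  VariantSet(records, nClasses = nClasses, exclusionLog = excl)
}

#' Write a VariantSet as TSV
#'
#' Inverse of \code{readVariantTable(..., format = "tsv")}: missing fields
#' become \code{"."}, scores are printed with full double precision so a
#' write/read/write cycle is byte-identical.
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVariantTable <- function(vs, path) {
  rec <- variantRecords(vs)
  out <- data.frame(
    variant_id = rec$variant_id,
    gene = ifelse(is.na(rec$gene), ".", rec$gene),
    score = sprintf("%.17g", rec$score),
    expert_class = ifelse(is.na(rec$expert_class), ".",
                          as.character(rec$expert_class)),
    impact = ifelse(is.na(rec$impact), ".", rec$impact),
    effect_label = ifelse(is.na(rec$effect_label), ".", rec$effect_label),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict to records usable for model fitting
#'
#' Keeps only records with a non-missing expert class and score, appending
#' the dropped rows to the exclusion log, and reports per-class counts.
#' A warning is raised when fewer than J distinct classes remain (the model
#' still fits but some cut-offs are data-starved).
#'
#' @param vs a \linkS4class{VariantSet}.
#' @return A \linkS4class{VariantSet} containing the fit subset.
#' @export
fitSubset <- function(vs) {
  rec <- variantRecords(vs)
  if (nrow(rec) == 0L) {
    warning("empty variant set")
    return(vs)
  }
  drop <- is.na(rec$expert_class) | is.na(rec$score)
  reason <- ifelse(is.na(rec$score[drop]), "missing score",
                   "missing expert_class")
  excl <- rbind(exclusionLog(vs),
                data.frame(variant_id = rec$variant_id[drop],
                           reason = reason,
                           stringsAsFactors = FALSE))
  kept <- rec[!drop, , drop = FALSE]
  counts <- table(factor(kept$expert_class, levels = seq_len(nClasses(vs))))
  message("fit subset: ", nrow(kept), " records; per-class counts: ",
          paste(counts, collapse = ", "))
  if (sum(counts > 0L) < nClasses(vs))
    warning("fewer than ", nClasses(vs), " distinct observed classes; ",
            "some cut-offs will be weakly identified")
  VariantSet(kept, nClasses = nClasses(vs), exclusionLog = excl)
}
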