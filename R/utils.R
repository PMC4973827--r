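## Internal numerical helpers shared across modules.

#' @importFrom stats plogis qlogis
NULL

## log(sigma(a) - sigma(b)) for a > b, computed without cancellation via
## sigma(a) - sigma(b) = sigma(a) * sigma(-b) * (1 - exp(b - a)).
## a = +Inf and b = -Inf are allowed (top / bottom class); the gap term
## vanishes there (and its Inf - Inf NaN is immaterial: plogis already
## yields the -Inf / 0 limit).
.logSigmoidDiff <- function(a, b) {
  out <- plogis(a, log.p = TRUE) + plogis(-b, log.p = TRUE)
  gap <- b - a                          # <= 0
  adj <- log1p(-exp(gap))
  adj[!is.finite(gap)] <- 0
  out + adj
}

## Deterministic sub-seed for a named generator substream, derived from one
## global seed. Kept strictly below 2^31 - 1.
.substreamSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

.isMissingToken <- function(x) {
  is.na(x) | x == "" | x == "."
}

.impactLevels <- c("MODIFIER", "LOW", "MODERATE", "HIGH")

## Collapse several impact annotations to the most severe one.
.maxImpact <- function(impacts) {
  impacts <- impacts[impacts %in% .impactLevels]
  if (length(impacts) == 0L) return(NA_character_)
  .impactLevels[max(match(impacts, .impactLevels))]
}
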