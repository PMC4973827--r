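# Shared fixtures. Expensive MCMC fits are computed once per test run and
# cached; every fixture is generated in code under a fixed seed.

.testCache <- new.env(parent = emptyenv())

# Sampler settings used for test fits: two chains are enough for PSRF and
# the posterior is unimodal and low-dimensional, so short adapted chains
# mix well at study-scale n.
testControl <- function(seed = 101L, nIter = 2500L, nBurnin = 1200L,
                        nChains = 2L) {
  clmControl(nChains = nChains, nIter = nIter, nBurnin = nBurnin,
             seed = seed)
}

# Emulated study-scale dataset (2,210 records) and its Bayesian fit.
studyFit <- function() {
  if (is.null(.testCache$study)) {
    vs <- suppressMessages(fitSubset(emulateInsight(seed = 101L)))
    draws <- fitBayes(vs, testControl())
    .testCache$study <- list(vs = vs, draws = draws)
  }
  .testCache$study
}

# Emulated study plus 15 structural-variant fixtures, and its fit.
structuralFit <- function() {
  if (is.null(.testCache$structural)) {
    base <- emulateInsight(seed = 101L)
    sv <- makeStructuralFixture(15L, seed = 202L)
    vs <- suppressMessages(fitSubset(bindVariantSets(base, sv)))
    draws <- fitBayes(vs, testControl())
    .testCache$structural <- list(vs = vs, draws = draws,
                                  svIds = variantRecords(sv)$variant_id)
  }
  .testCache$structural
}

# A small, fully valid five-row TSV on disk; returns the path.
writeTinyTsv <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    variant_id = c("MLH1:c.1A>G", "MSH2:c.2C>T", "MSH6:c.3G>A",
                   "PMS2:c.4T>C", "MLH1:c.5del"),
    gene = c("MLH1", "MSH2", "MSH6", "PMS2", "MLH1"),
    score = c("25.1", "3.2", "-1.5", "14.85", "33"),
    expert_class = c("5", "1", "2", "3", "."),
    impact = c("MODERATE", "LOW", ".", "MODERATE", "HIGH"),
    effect_label = c("NON_SYNONYMOUS_CODING", ".", ".", ".", "FRAME_SHIFT"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A minimal VCF 4.2 with the score in INFO and SnpEff-style ANN entries;
# includes one multi-allelic record and one ambiguous alt allele.
writeTinyVcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CADD_SCALED,Number=A,Type=Float,Description=\"Scaled deleteriousness score\">",
    "##INFO=<ID=EXPERT_CLASS,Number=A,Type=Integer,Description=\"Expert ordinal class\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations: 'Allele|Annotation|Annotation_Impact|Gene_Name'\">",
    "##contig=<ID=chr3>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr3\t100\tv1\tA\tG\t.\t.\t",
           "CADD_SCALED=25.1;EXPERT_CLASS=5;",
           "ANN=G|missense_variant|MODERATE|MLH1,G|intron_variant|MODIFIER|MLH1"),
    paste0("chr3\t200\tv2\tC\tT,G\t.\t.\t",
           "CADD_SCALED=3.2,4.4;EXPERT_CLASS=1,1;",
           "ANN=T|synonymous_variant|LOW|MLH1"),
    paste0("chr3\t300\tv3\tT\tR\t.\t.\t",
           "CADD_SCALED=9.9;EXPERT_CLASS=3"),
    paste0("chr3\t400\tv4\tG\tA\t.\t.\t",
           "CADD_SCALED=41;EXPERT_CLASS=3;",
           "ANN=A|stop_gained|HIGH|MLH1"))
  writeLines(lines, path)
  path
}
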