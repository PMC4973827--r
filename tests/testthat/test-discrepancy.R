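# Posterior mean-deviance flagging, reassignment bookkeeping, Spearman.

# Draws collapsed to a single stored parameter set.
singleDraw <- function(theta, beta, J = 5L) {
  a <- array(rep(c(theta, beta), each = 2), dim = c(2, length(theta) + 1, 2),
             dimnames = list(NULL,
                             c(paste0("theta", seq_along(theta)), "beta1"),
                             NULL))
  new("PosteriorDraws", draws = a, nClasses = J, nBurnin = 0L, seed = 1L,
      psrf = rep(1, length(theta) + 1), converged = TRUE,
      acceptance = numeric())
}

test_that("constant draws give the point deviance as the mean deviance", {
  theta <- c(-2, -1, 1, 2); beta <- 0.3
  vs <- suppressMessages(fitSubset(
    generateFromCLM(CLMParameters(theta, beta), rnorm(40, 0, 5), seed = 2)))
  draws <- singleDraw(theta, beta)
  prof <- meanDeviances(draws, vs)
  p <- CLMParameters(theta, beta)
  rec <- variantRecords(vs)
  expected <- mapply(function(s, y) observationDeviance(p, s, y),
                     rec$score, rec$expert_class)
  expect_equal(prof@profile$mean_deviance, unname(expected),
               tolerance = 1e-12)
  # point-estimate switch agrees when the posterior is a point mass
  prof2 <- meanDeviances(draws, vs, pointEstimate = TRUE)
  expect_equal(prof2@profile$mean_deviance, prof@profile$mean_deviance,
               tolerance = 1e-12)
})

test_that("identical records are never flagged (strict threshold rule)", {
  df <- data.frame(variant_id = paste0("v", 1:50), score = 10,
                   expert_class = 3L)
  vs <- VariantSet(df)
  prof <- meanDeviances(singleDraw(c(-2, -1, 1, 2), 0.1), vs)
  expect_identical(sum(prof@profile$flagged), 0L)
})

test_that("flagged fraction respects the 5% + 1/n construction bound", {
  fit <- studyFit()
  prof <- meanDeviances(fit$draws, fit$vs)
  n <- nVariants(fit$vs)
  frac <- mean(prof@profile$flagged)
  expect_gte(frac, 0)
  expect_lte(frac, 0.05 + 1 / n)
  expect_identical(prof@profile$flagged,
                   prof@profile$mean_deviance > prof@threshold)
})

test_that("no flagged records yields a diagonal matrix and zero discordance", {
  df <- data.frame(variant_id = paste0("v", 1:50), score = 10,
                   expert_class = 3L)
  vs <- VariantSet(df)
  draws <- singleDraw(c(-2, -1, 1, 2), 0.1)
  prof <- meanDeviances(draws, vs)
  rep0 <- reassign(prof, draws, vs)
  expect_identical(rep0@nDiscordant, 0L)
  expect_identical(sum(reassignmentMatrix(rep0)) -
                     sum(diag(reassignmentMatrix(rep0))), 0L)
})

test_that("reassignment matrix columns reproduce per-class counts", {
  fit <- studyFit()
  prof <- meanDeviances(fit$draws, fit$vs)
  rep1 <- reassign(prof, fit$draws, fit$vs)
  m <- reassignmentMatrix(rep1)
  counts <- as.integer(table(variantRecords(fit$vs)$expert_class))
  expect_identical(as.integer(colSums(m)), counts)
  # unflagged variants contribute only to the diagonal
  asg <- assignments(rep1)
  expect_true(all(asg$model_class[!asg$flagged] ==
                    asg$expert_class[!asg$flagged]))
  # discordance never exceeds the number flagged
  expect_lte(rep1@nDiscordant, rep1@nFlagged)
  expect_identical(rep1@nDiscordant,
                   sum(asg$model_class != asg$expert_class))
  # false positive/negative extraction matches the matrix corners
  expect_identical(length(falsePositives(rep1)), m[5, 1])
  expect_identical(length(falseNegatives(rep1)), m[1, 5])
})

test_that("only flagged variants with a changed argmax count as discordant", {
  # one extreme class-1 outlier whose argmax moves to class 5
  df <- data.frame(variant_id = paste0("v", 1:40),
                   score = c(rep(0, 39), 60),
                   expert_class = c(rep(3L, 39), 1L))
  vs <- VariantSet(df)
  draws <- singleDraw(c(-2, -1, 1, 2), 0.25)
  prof <- meanDeviances(draws, vs)
  expect_true(prof@profile$flagged[40])
  rep1 <- reassign(prof, draws, vs)
  asg <- assignments(rep1)
  expect_identical(asg$model_class[40], 5L)     # argmax at score 60
  expect_identical(rep1@nDiscordant, 1L)
  expect_identical(falsePositives(rep1), "v40")

  # a flagged variant whose argmax equals its expert class stays diagonal
  df2 <- data.frame(variant_id = paste0("w", 1:40),
                    score = c(rep(0, 39), 2),
                    expert_class = rep(3L, 40))
  vs2 <- VariantSet(df2)
  prof2 <- meanDeviances(draws, vs2)
  expect_true(prof2@profile$flagged[40])
  rep2 <- reassign(prof2, draws, vs2)
  expect_identical(rep2@nDiscordant, 0L)
  expect_identical(rep2@nFlagged, 1L)
})

test_that("Spearman matches independent computations exactly", {
  set.seed(9)
  df <- data.frame(variant_id = paste0("v", 1:50),
                   score = round(rnorm(50, 10, 5), 1),   # induces ties
                   expert_class = sample(1:5, 50, replace = TRUE))
  vs <- VariantSet(df)
  out <- spearmanClassScore(vs)
  # oracle 1: stats' own Spearman
  expect_equal(out$rho,
               cor(df$expert_class, df$score, method = "spearman"),
               tolerance = 1e-12)
  # oracle 2: brute-force midranks then the Pearson product-moment formula
  rx <- rank(df$expert_class); ry <- rank(df$score)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(out$rho, oracle, tolerance = 1e-12)
})

test_that("Spearman edge cases: monotone data, degenerate input", {
  df <- data.frame(variant_id = paste0("v", 1:5), score = 1:5 * 2,
                   expert_class = 1:5)
  expect_equal(spearmanClassScore(VariantSet(df))$rho, 1.0)
  dfc <- data.frame(variant_id = paste0("v", 1:5), score = rep(1, 5),
                    expert_class = 1:5)
  expect_error(spearmanClassScore(VariantSet(dfc)), "zero variance")
  expect_error(spearmanClassScore(VariantSet(df[1:2, ])), "at least 3")
})
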