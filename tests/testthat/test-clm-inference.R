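# MCMC sampler, convergence diagnostics and the ML cross-check.

# Hand-built PosteriorDraws for diagnostic unit tests.
makeDraws <- function(a, J = 5L) {
  new("PosteriorDraws", draws = a, nClasses = J, nBurnin = 0L, seed = 1L,
      psrf = rep(NA_real_, dim(a)[2]), converged = NA, acceptance = numeric())
}

test_that("fitBayes is bit-identical given the same data, settings and seed", {
  vs <- suppressMessages(fitSubset(
    generateFromCLM(CLMParameters(c(-2, -1, 1, 2), 0.25),
                    scores = rnorm(300, 0, 10), seed = 9)))
  ctl <- clmControl(nChains = 2, nIter = 400, nBurnin = 200, seed = 33)
  f1 <- suppressWarnings(fitBayes(vs, ctl))
  f2 <- suppressWarnings(fitBayes(vs, ctl))
  expect_identical(f1@draws, f2@draws)
  # and every stored draw respects the cut-off ordering
  th <- f1@draws[, 1:4, ]
  expect_true(all(apply(th, c(1, 3), function(v) all(diff(v) > 0))))
})

test_that("seed is mandatory and degenerate data are rejected", {
  vs <- VariantSet(data.frame(variant_id = letters[1:10], score = 1:10,
                              expert_class = rep(3L, 10)))
  expect_error(fitBayes(vs, clmControl()), "seed")
  expect_error(fitBayes(vs, clmControl(seed = 1)), "one class")
})

test_that("with no data the posterior recovers the prior on beta", {
  ctl <- clmControl(nChains = 2, nIter = 3000, nBurnin = 1000, seed = 4,
                    priorSd = 10, priorOnly = TRUE)
  vs <- VariantSet(data.frame(variant_id = "a", score = 1,
                              expert_class = 1L))
  fit <- suppressWarnings(fitBayes(vs, ctl))
  s <- summarizePosterior(fit)
  bmean <- s$mean[s$parameter == "beta1"]
  bsd <- s$sd[s$parameter == "beta1"]
  # prior is Normal(0, 10); Monte-Carlo error on the mean of correlated
  # draws is generous
  expect_lt(abs(bmean), 2.5)
  expect_gt(bsd, 5)
})

test_that("split PSRF is 1 for identical chains and large for shifted ones", {
  set.seed(1)
  base <- matrix(rnorm(500 * 5), 500, 5,
                 dimnames = list(NULL, c(paste0("theta", 1:4), "beta1")))
  a <- array(c(base, base), dim = c(500, 5, 2),
             dimnames = list(NULL, colnames(base), NULL))
  expect_equal(unname(psrf(makeDraws(a), rankNormalized = FALSE)),
               rep(1, 5), tolerance = 1e-12)
  shifted <- array(c(base, base + 50), dim = c(500, 5, 2),
                   dimnames = dimnames(a))
  expect_true(all(psrf(makeDraws(shifted)) > 1.1))
})

test_that("PSRF is near 1 for iid chains from a common distribution", {
  set.seed(2)
  a <- array(rnorm(2000 * 5 * 4), dim = c(2000, 5, 4),
             dimnames = list(NULL, c(paste0("theta", 1:4), "beta1"), NULL))
  r <- psrf(makeDraws(a))
  expect_true(all(r < 1.02))
  expect_error(psrf(makeDraws(a[, , 1, drop = FALSE])), "2 chains")
})

test_that("posterior summaries behave on degenerate and synthetic draws", {
  cn <- list(NULL, c(paste0("theta", 1:4), "beta1"), NULL)
  const <- array(rep(c(-2, -1, 1, 2, 0.3), each = 100), dim = c(100, 5, 2))
  dimnames(const) <- cn
  s <- summarizePosterior(makeDraws(const))
  expect_equal(s$sd, rep(0, 5))
  expect_equal(s$lower, s$mean)
  expect_equal(s$upper, s$mean)
  expect_equal(s$mean, c(-2, -1, 1, 2, 0.3))

  set.seed(8)
  z <- array(rnorm(20000 * 5 * 2), dim = c(20000, 5, 2), dimnames = cn)
  sz <- summarizePosterior(makeDraws(z))
  expect_equal(sz$mean, rep(0, 5), tolerance = 0.05)
  expect_equal(sz$lower, rep(-1.96, 5), tolerance = 0.05)
  expect_equal(sz$upper, rep(1.96, 5), tolerance = 0.05)

  # permutation invariance to iteration order
  perm <- const[sample(100), , , drop = FALSE]
  dimnames(perm) <- cn
  expect_equal(summarizePosterior(makeDraws(perm)), s)
})

test_that("ML estimates recover known parameters within 3 standard errors", {
  truth <- CLMParameters(theta = c(-6, -4, 0, 4), beta = 0.25)
  set.seed(14)
  vs <- suppressMessages(fitSubset(
    generateFromCLM(truth, scores = rnorm(5000, 0, 20), seed = 14)))
  est <- fitML(vs)
  # asymptotic SEs at this n are below ~0.2 for theta, ~0.01 for beta;
  # use simulation-calibrated slack of 3 SE
  expect_lt(max(abs(thetaCutoffs(est) - c(-6, -4, 0, 4))), 0.6)
  expect_lt(abs(betaWeights(est) - 0.25), 0.03)
  expect_lte(attr(est, "logLik"), 0)
})

test_that("ML agrees with the independent proportional-odds fit from MASS", {
  truth <- CLMParameters(theta = c(-2, -0.5, 1, 3), beta = 0.4)
  set.seed(21)
  scores <- rnorm(800, 0, 6)
  vs <- suppressMessages(fitSubset(generateFromCLM(truth, scores, seed = 21)))
  est <- fitML(vs)
  rec <- variantRecords(vs)
  po <- MASS::polr(factor(expert_class, ordered = TRUE) ~ score,
                   data = rec, method = "logistic")
  expect_equal(unname(thetaCutoffs(est)), unname(po$zeta), tolerance = 1e-3)
  expect_equal(unname(betaWeights(est)), unname(po$coefficients),
               tolerance = 1e-3)
})

test_that("posterior mean matches the MLE on large data with vague priors", {
  truth <- CLMParameters(theta = c(-2, -0.5, 1, 3), beta = 0.4)
  vs <- suppressMessages(fitSubset(
    generateFromCLM(truth, scores = rnorm(2000, 0, 6), seed = 31)))
  ml <- fitML(vs)
  fit <- fitBayes(vs, clmControl(nChains = 2, nIter = 2000, nBurnin = 1000,
                                 seed = 31))
  s <- summarizePosterior(fit)
  mle <- c(thetaCutoffs(ml), betaWeights(ml))
  # Bernstein-von-Mises-style agreement within Monte-Carlo error
  expect_true(all(abs(s$mean - mle) < 3 * s$sd / sqrt(10) + 0.05))
})

test_that("complete separation is detected and reported", {
  df <- data.frame(variant_id = paste0("v", 1:40),
                   score = c(rnorm(20, -10, 1), rnorm(20, 10, 1)),
                   expert_class = rep(c(1L, 2L), each = 20))
  vs <- VariantSet(df, nClasses = 2L)
  expect_warning(fitML(vs), "separation")
})
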