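# Core proportional-odds math: probabilities, likelihood, deviance,
# assignment. Oracles are direct logistic-CDF evaluations, independent of
# the package's stable log-sigmoid-difference path.

test_that("cumulative and class probabilities match the logistic-CDF oracle", {
  p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 0)
  expect_equal(cumulativeProbs(p, 0),
               c(plogis(c(-2, -1, 1, 2)), 1), tolerance = 1e-12)
  cp <- classProbs(p, 0)
  oracle <- diff(c(0, plogis(c(-2, -1, 1, 2)), 1))
  expect_equal(cp$probs, oracle, tolerance = 1e-12)
  expect_equal(cp$cumulative, cumsum(oracle), tolerance = 1e-12)

  # random parameter sets, exact agreement with the naive CDF differences
  set.seed(42)
  for (i in 1:25) {
    theta <- sort(rnorm(4, 0, 3))
    beta <- rnorm(1)
    x <- rnorm(1, 0, 10)
    pp <- CLMParameters(theta, beta)
    naive <- diff(c(0, plogis(theta - x * beta), 1))
    expect_equal(classProbs(pp, x)$probs, naive, tolerance = 1e-12)
  }
})

test_that("J = 2 with zero cut-off and slope splits mass evenly", {
  p <- CLMParameters(theta = 0, beta = 0)
  expect_equal(cumulativeProbs(p, 123.4), c(0.5, 1.0))
})

test_that("probabilities are a valid distribution for arbitrary parameters", {
  set.seed(7)
  for (i in 1:50) {
    p <- CLMParameters(sort(rnorm(4, 0, 5)), rnorm(1))
    x <- rnorm(1, 0, 50)
    probs <- classProbs(p, x)$probs
    expect_true(all(probs >= 0) && all(probs <= 1))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_true(all(diff(cumulativeProbs(p, x)) >= 0))
  }
})

test_that("with beta = 0 the covariate drops out", {
  p <- CLMParameters(theta = c(-1, 0, 1, 3), beta = 0)
  expect_identical(classProbs(p, -500)$probs, classProbs(p, 500)$probs)
})

test_that("positive slope pushes cumulative mass down and class up", {
  p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 1)
  lo <- cumulativeProbs(p, -5)
  hi <- cumulativeProbs(p, 5)
  expect_true(all(hi[1:4] <= lo[1:4]))
  # extreme score: all mass in the top class
  expect_lt(max(cumulativeProbs(p, 60)[1:4]), 1e-12)
  expect_equal(assignClass(p, 60), 5L)
})

test_that("probabilities stay finite and normalized for extreme scores", {
  # scaled scores for structural variants can reach the hundreds
  p <- CLMParameters(theta = c(-0.4, 0.15, 2.8, 3.2), beta = 0.14)
  for (x in c(-550, -40, 350, 550)) {
    probs <- classProbs(p, x)$probs
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_false(anyNA(probs))
  }
})

test_that("log-likelihood is additive and matches the class-probability oracle", {
  p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 0)
  one <- VariantSet(data.frame(variant_id = "a", score = 0,
                               expert_class = 3L))
  expect_equal(logLikelihood(p, one),
               log(diff(plogis(c(-1, 1)))), tolerance = 1e-12)
  two <- VariantSet(data.frame(variant_id = c("a", "b"), score = c(0, 0),
                               expert_class = c(3L, 3L)))
  expect_equal(logLikelihood(p, two), 2 * logLikelihood(p, one))
  expect_lte(logLikelihood(p, two), 0)
  expect_warning(ll0 <- logLikelihood(p, VariantSet(
    data.frame(variant_id = character(), score = numeric(),
               expert_class = integer()))), "empty")
  expect_identical(ll0, 0)
})

test_that("a certain observation has likelihood 1 and deviance 0", {
  # theta so extreme that class 1 has probability ~1 at x = 0
  p <- CLMParameters(theta = c(800, 900), beta = 0)
  expect_equal(observationDeviance(p, 0, 1L), 0)
  one <- VariantSet(data.frame(variant_id = "a", score = 0,
                               expert_class = 1L), nClasses = 3L)
  expect_equal(logLikelihood(p, one), 0)
})

test_that("deviance equals -2 log P and decreases in P", {
  p <- CLMParameters(theta = 0, beta = 0)          # J = 2, P = 0.5
  expect_equal(observationDeviance(p, 3.7, 1L), 2 * log(2),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    pp <- CLMParameters(sort(rnorm(4)), rnorm(1))
    x <- rnorm(1, 0, 5)
    probs <- classProbs(pp, x)$probs
    dev <- vapply(1:5, function(j) observationDeviance(pp, x, j), 0)
    expect_equal(dev, -2 * log(probs), tolerance = 1e-10)
    expect_equal(order(dev), order(-probs))
  }
  # the logit link never yields an exactly-zero probability: a class far
  # beyond the cut-offs keeps its exact log-scale deviance -2 log sigma(-900)
  pZ <- CLMParameters(theta = c(800, 900), beta = 0)
  expect_equal(observationDeviance(pZ, 0, 3L), 1800, tolerance = 1e-12)
})

test_that("log-likelihood equals minus half the summed deviances", {
  set.seed(3)
  p <- CLMParameters(sort(rnorm(4)), 0.3)
  df <- data.frame(variant_id = paste0("v", 1:30),
                   score = rnorm(30, 0, 5),
                   expert_class = sample(1:5, 30, replace = TRUE))
  vs <- VariantSet(df)
  devs <- mapply(function(s, y) observationDeviance(p, s, y),
                 df$score, df$expert_class)
  expect_equal(logLikelihood(p, vs), -sum(devs) / 2, tolerance = 1e-10)
})

test_that("class assignment is the argmax with ties to the lower index", {
  p <- CLMParameters(theta = c(-2, -1, 1, 2), beta = 0)
  expect_identical(assignClass(p, 0), 3L)
  # exact two-way tie: J = 2, cut-off at the linear predictor -> (0.5, 0.5)
  pt <- CLMParameters(theta = 0, beta = 0)
  expect_equal(classProbs(pt, 0)$probs, c(0.5, 0.5))
  expect_identical(assignClass(pt, 0), 1L)
})

test_that("non-finite covariates are rejected", {
  p <- CLMParameters(theta = c(-1, 1), beta = 1)
  expect_error(classProbs(p, NA_real_), "finite")
  expect_error(cumulativeProbs(p, Inf), "finite")
})

test_that("parameter validity is enforced", {
  expect_error(CLMParameters(theta = c(1, -1), beta = 0), "increasing")
  expect_error(CLMParameters(theta = c(0, Inf), beta = 0), "finite")
})
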