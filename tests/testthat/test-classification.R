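test_that("model fitting reproduces the smoothing formula", {
  m0 <- fitModel(c("A", "B", "A", "B"), alpha = 0)
  expect_equal(probs(m0)[1, 2], 1)
  m1 <- fitModel(c("A", "B", "A", "B"), alpha = 1, alphabet = c("A", "B"))
  expect_equal(probs(m1)[1, 2], (2 + 1) / (2 + 2))
  expect_true(all(probs(m1) > 0))
  expect_equal(unname(rowSums(probs(m1))), c(1, 1), tolerance = 1e-9)
  expect_error(fitModel("A"), "insufficient")
})

test_that("log-likelihood sums log transition probabilities", {
  det <- fitModel(c("A", "B", "C", "A", "B", "C", "A"), alpha = 0)
  expect_equal(logLikSequence(c("A", "B", "C", "A"), det), 0)
  mod <- new("TransitionModel", alphabet = c("A", "B"),
             counts = matrix(0L, 2, 2),
             probs = matrix(c(0.5, 1, 0.5, 0), 2, 2),
             supported = c(TRUE, TRUE), alpha = 0)
  expect_equal(logLikSequence(c("A", "A", "B"), mod), 2 * log(0.5))
  # unseen transition under an unsmoothed model is flagged -Inf
  ll <- logLikSequence(c("B", "B"), mod)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(attr(ll, "zeroTransition"))
  expect_error(logLikSequence(c("A", "Z"), mod), "invalid symbol")
})

test_that("the unsmoothed fit is the likelihood maximizer", {
  set.seed(81)
  tok <- sampleMarkovSequence(randomStochasticMatrix(LETTERS[1:3]), 400)
  mle <- fitModel(tok, alpha = 0)
  llMle <- logLikSequence(tok, mle)
  for (i in 1:100) {
    Q <- randomStochasticMatrix(LETTERS[1:3])
    alt <- new("TransitionModel", alphabet = LETTERS[1:3],
               counts = matrix(0L, 3, 3), probs = unname(Q),
               supported = rep(TRUE, 3), alpha = 0)
    expect_gte(llMle, logLikSequence(tok, alt))
  }
})

test_that("hold-out split keeps the last k events plus their pauses", {
  set.seed(82)
  tok <- sample(c(LETTERS[1:3], "$"), 900, TRUE, prob = c(1, 1, 1, 1) / 4)
  times <- cumsum(runif(sum(tok != "$"), 0.08, 0.2))
  sq <- SymbolSequence(tok, times, "s", "ctrl_1", "ctrl", 0.12)
  sp <- splitHoldout(sq, 100)
  expect_equal(sum(tokens(sp$test) != "$"), 100)
  expect_identical(c(tokens(sp$train), tokens(sp$test)), tok)
  expect_identical(c(eventTimes(sp$train), eventTimes(sp$test)), times)
  expect_error(splitHoldout(sq, 10000), "insufficient")
  # 100 events at a mean gap near 0.12 s span roughly 12 s
  times12 <- cumsum(rep(0.12, 700))
  sq12 <- SymbolSequence(rep("A", 700), times12, pauseDuration = 0.12)
  sp12 <- splitHoldout(sq12, 100)
  span <- diff(range(eventTimes(sp12$test)))
  expect_equal(span, 12, tolerance = 0.05)
})

test_that("prediction ranks candidates by likelihood", {
  sqA <- SymbolSequence(rep(c("A", "B"), 100), stepId = "ctrl_1",
                        maneuver = "ctrl")
  mod <- fitModel(sqA, alpha = 0.5, alphabet = c("A", "B", "C"))
  pred <- predictStep(sqA, list(ctrl_1 = mod))
  expect_equal(pred$predictedStep, "ctrl_1")
  expect_equal(pred$maneuverRank, 1L)
  # separated two-state experiment: high accuracy at 100 events
  shapes <- LETTERS[1:8]
  mats <- maneuverMatrices(shapes, c("ctrl", "capsa"), seed = 83)
  states <- list(stateSpec("ctrl", mats$ctrl, 2, 1500),
                 stateSpec("capsa", mats$capsa, 2, 1500))
  ex <- makeExperiment(states, nSegments = 5, seed = 84, render = FALSE)
  rep100 <- evaluateExperiment(ex@truthSymbols, kLengths = 100)
  expect_gte(rep100$accuracyByK$accuracyPct[1], 90)
  expect_error(predictStep(sqA, list()), "invalid")
})

test_that("evaluation reaches 100% in the perfect-separation limit", {
  # disjoint alphabet usage per maneuver
  A1 <- matrix(0, 5, 5, dimnames = list(c("A", "B", "$", "C", "D"),
                                        c("A", "B", "$", "C", "D")))
  A1[, "A"] <- 0.45; A1[, "B"] <- 0.45; A1[, "$"] <- 0.1
  A2 <- matrix(0, 5, 5, dimnames = dimnames(A1))
  A2[, "C"] <- 0.45; A2[, "D"] <- 0.45; A2[, "$"] <- 0.1
  states <- list(stateSpec("ctrl", A1, 2, 800),
                 stateSpec("capsa", A2, 2, 800))
  ex <- makeExperiment(states, nSegments = 3, seed = 85, render = FALSE,
                       perturbWeight = 0)
  repPS <- evaluateExperiment(ex@truthSymbols, kLengths = c(50, 100))
  expect_equal(repPS$accuracyByK$accuracyPct, c(100, 100))
})

test_that("top-k success is monotone and saturates", {
  ex <- makeE130221Experiment(seed = 86, symbolsPerStep = 800, nSegments = 3)
  repK <- evaluateExperiment(ex@truthSymbols, kLengths = 100)
  tk <- topkRates(repK$predictions, ks = 1:8)
  expect_true(all(diff(tk$successPct) >= 0))
  expect_equal(tk$successPct[8], 100)
  expect_equal(tk$successPct[1], repK$accuracyByK$accuracyPct[1])
  expect_error(topkRates(repK$predictions, ks = 0), "invalid")
})

test_that("consensus takes the modal maneuver and helps accuracy", {
  expect_equal(consensusManeuver(c(rep("ctrl", 6), rep("capsa", 5))), "ctrl")
  expect_equal(consensusManeuver("esp"), "esp")
  # tie broken by summed log-likelihood
  expect_equal(consensusManeuver(c("a", "b"), c(-10, -5)), "b")
  set.seed(87)
  diffs <- vapply(1:5, function(i) {
    ex <- makeE130221Experiment(seed = 870 + i, symbolsPerStep = 600,
                                nSegments = 11, separation = 0.2)
    repC <- evaluateExperiment(ex@truthSymbols, kLengths = 50)
    100 * mean(repC$consensus$success) - repC$accuracyByK$accuracyPct[1]
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("the Monte-Carlo baseline matches the analytic value", {
  expect_equal(analyticBaseline(c(ctrl = 2, capsa = 3)), 52)
  expect_equal(analyticBaseline(c(ctrl = 2, esp = 2, capsa = 4)), 37.5)
  expect_equal(randomBaseline(c(only = 4), seed = 1), 100)
  set.seed(88)
  for (i in 1:20) {
    counts <- sample(1:5, sample(2:4, 1), TRUE)
    mc <- randomBaseline(counts, nTrials = 10000)
    an <- analyticBaseline(counts)
    se <- 100 * sqrt(an / 100 * (1 - an / 100) / 10000)
    expect_lt(abs(mc - an), max(3 * se, 1e-9))
  }
  expect_error(randomBaseline(numeric()), "invalid")
})

test_that("smoothing keeps rankings stable as alpha vanishes", {
  ex <- makeE130221Experiment(seed = 89, symbolsPerStep = 800, nSegments = 2)
  seqs <- ex@truthSymbols[1:8]
  sp <- lapply(seqs, splitHoldout, kEvents = 50)
  ab <- c(LETTERS[1:12], "$")
  for (alpha in c(1, 0.5, 0.01)) {
    models <- lapply(sp, function(s) fitModel(s$train, alpha, ab))
    lls <- vapply(models, function(m)
      as.numeric(logLikSequence(sp[[1]]$test, m)), 0)
    expect_true(all(is.finite(lls)))
  }
  # alpha -> 0 ranking converges to the unsmoothed one when all test
  # transitions were seen in training
  m0 <- lapply(sp, function(s) fitModel(s$train, 0, ab))
  ll0 <- vapply(m0, function(m) as.numeric(logLikSequence(sp[[1]]$test, m)), 0)
  if (all(is.finite(ll0))) {
    mEps <- lapply(sp, function(s) fitModel(s$train, 1e-8, ab))
    llE <- vapply(mEps, function(m)
      as.numeric(logLikSequence(sp[[1]]$test, m)), 0)
    expect_equal(order(ll0), order(llE))
  }
})
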