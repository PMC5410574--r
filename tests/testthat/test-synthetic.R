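test_that("templates are distinct, centre-peaked, band-limited and reproducible", {
  tpl <- makeTemplates(12, seed = 1)
  w <- prototypes(tpl)
  expect_equal(dim(w), c(12L, 1000L))
  # pairwise distinctness against the default noise level (brute force)
  D <- as.matrix(dist(w))
  diag(D) <- Inf
  expect_gt(min(D), 5 * defaultNoiseSd)
  # positive maximum within the central fifth of the window
  for (i in 1:12) {
    pk <- which.max(abs(w[i, ]))
    expect_equal(pk, which.max(w[i, ]))
    expect_gte(pk, 400)
    expect_lte(pk, 600)
  }
  # content survives the 70 Hz detection smoothing nearly unchanged
  sm <- lowpassSmooth(w[1, ], 10000, 70)
  expect_lt(max(abs(sm - w[1, ])), 0.05 * max(abs(w[1, ])))
  expect_equal(prototypes(makeTemplates(12, seed = 1)), w)
  # degenerate single-template case and invalid argument
  expect_equal(nrow(prototypes(makeTemplates(1, seed = 2))), 1L)
  expect_error(makeTemplates(0), "invalid")
})

test_that("markov sampling follows the transition matrix", {
  ab <- c("A", "B", "C")
  P <- matrix(0, 3, 3, dimnames = list(ab, ab))
  P["A", "B"] <- P["B", "C"] <- P["C", "A"] <- 1
  expect_equal(sampleMarkovSequence(P, 6, startDistribution = c(1, 0, 0),
                                    seed = 1),
               c("A", "B", "C", "A", "B", "C"))
  # law of large numbers: empirical conditional frequencies approach P
  Q <- randomStochasticMatrix(ab, concentration = 2, seed = 3)
  tok <- sampleMarkovSequence(Q, 1e5, seed = 4)
  est <- probs(transitionProbs(pairCounts(tok, ab)))
  expect_lt(max(abs(est - Q)), 0.01)
  bad <- Q; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(sampleMarkovSequence(bad, 10), "invalid model")
  expect_error(sampleMarkovSequence(Q, 0), "invalid")
})

test_that("iid rows pass the order-1 independence test", {
  ab <- LETTERS[1:5]
  P <- matrix(1 / 5, 5, 5, dimnames = list(ab, ab))
  set.seed(11)
  rej <- 0
  for (r in 1:100) {
    tok <- sampleMarkovSequence(P, 1500)
    if (pValue(chi2TestOrder1(tok, ab)) <= 0.05) rej <- rej + 1
  }
  expect_lte(rej, 10)  # test holds level in >= 90% of replicates
})

test_that("rendering places events by the stated spacing rule", {
  tpl <- makeTemplates(3, seed = 5)
  # noiseless single event reproduces the template at its truth time
  r <- renderRecording("A", tpl, 0.12, jitterSdS = 0, noiseSd = 0)
  expect_equal(length(r$truthTimes), 1L)
  wA <- prototypes(tpl)[1, ]
  i0 <- which.max(samples(r$recording)) - which.max(wA) + 1
  expect_equal(samples(r$recording)[i0:(i0 + 999)], unname(wA))
  # truth time sits at the smoothed maximum, close to the raw one
  expect_lt(abs(r$truthTimes - (which.max(samples(r$recording)) - 1) / 1e4),
            0.005)
  # pauses advance time by whole pause periods
  r2 <- renderRecording(c("A", "$", "$", "B"), tpl, 0.12, jitterSdS = 0,
                        noiseSd = 0)
  gap <- diff(r2$truthTimes)
  expect_gt(gap, 2 * 0.12)        # two whole pauses elapsed
  expect_lt(gap, 3 * 0.12)        # but less than three
  # truth-time conservation: one per non-pause token, strictly increasing
  set.seed(6)
  tok <- sample(c("A", "B", "C", "$"), 200, TRUE)
  r3 <- renderRecording(tok, tpl, 0.12, seed = 7)
  expect_equal(length(r3$truthTimes), sum(tok != "$"))
  expect_true(all(diff(r3$truthTimes) > 0))
  expect_error(renderRecording(c("A", "Z"), tpl), "invalid symbol")
})

test_that("synthetic experiments are reproducible and complete", {
  shapes <- LETTERS[1:4]
  mats <- maneuverMatrices(shapes, c("ctrl", "esp", "capsa"), seed = 1)
  states <- list(stateSpec("ctrl", mats$ctrl, 2, 300),
                 stateSpec("esp", mats$esp, 2, 300),
                 stateSpec("capsa", mats$capsa, 4, 300))
  ex <- makeExperiment(states, nSegments = 1, seed = 9, render = FALSE)
  expect_equal(length(ex@truthSymbols), 8L)  # ctrl(2) esp(2) capsa(4)
  ex11 <- makeExperiment(states, nSegments = 11, seed = 9, render = FALSE)
  expect_equal(length(ex11@truthSymbols), 88L)
  expect_equal(length(unique(vapply(ex11@truthSymbols, segmentId, ""))), 11L)
  # determinism: identical seeds give identical experiments
  ex2 <- makeExperiment(states, nSegments = 1, seed = 9, render = FALSE)
  expect_identical(lapply(ex@truthSymbols, tokens),
                   lapply(ex2@truthSymbols, tokens))
  expect_identical(lapply(ex@truthSymbols, eventTimes),
                   lapply(ex2@truthSymbols, eventTimes))
  expect_error(makeExperiment(list(), 1), "invalid")
})

test_that("truth pair counts recover the generating matrix", {
  ab <- c(LETTERS[1:5], "$")
  Q <- randomStochasticMatrix(ab, concentration = 5, seed = 2)
  states <- list(stateSpec("ctrl", Q, 1, 3000))
  ex <- makeExperiment(states, nSegments = 1, seed = 3, render = FALSE,
                       perturbWeight = 0)
  tok <- tokens(ex@truthSymbols[[1]])
  est <- probs(transitionProbs(pairCounts(tok, ab)))
  expect_lt(max(abs(est - Q)), 0.05)
})

test_that("maneuver matrices have the promised row separation", {
  mats <- maneuverMatrices(LETTERS[1:12], c("ctrl", "esp", "capsa"),
                           seed = 4)
  rowTV <- function(A, B)
    min(vapply(seq_len(nrow(A)),
               function(i) 0.5 * sum(abs(A[i, ] - B[i, ])), 0))
  pairs <- combn(names(mats), 2)
  for (j in seq_len(ncol(pairs)))
    expect_gte(rowTV(mats[[pairs[1, j]]], mats[[pairs[2, j]]]), 0.3)
  for (M in mats) expect_equal(unname(rowSums(M)), rep(1, 13))
})
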