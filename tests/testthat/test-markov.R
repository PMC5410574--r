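test_that("pair counts enumerate adjacent pairs exactly", {
  N <- pairCounts(c("A", "B", "A", "B"))
  expect_equal(N["A", "B"], 2L)
  expect_equal(N["B", "A"], 1L)
  expect_equal(sum(N), 3L)
  expect_equal(pairCounts(c("A", "A", "A", "A"))["A", "A"], 3L)
  # conservation for arbitrary sequences, pauses included
  set.seed(61)
  tok <- sample(c("A", "B", "C", "$"), 500, TRUE)
  expect_equal(sum(pairCounts(tok)), 499L)
  expect_equal(rownames(pairCounts(tok)), c("A", "B", "C", "$"))
  expect_error(pairCounts("A"), "insufficient")
})

test_that("transition probabilities normalize rows and flag empty ones", {
  m1 <- transitionProbs(pairCounts(c("A", "B", "A", "B")))
  P1 <- probs(m1)
  expect_equal(P1[1, 2], 1)
  expect_equal(P1[2, 1], 1)
  m2 <- transitionProbs(pairCounts(c("A", "A", "B", "A", "B")))
  P2 <- probs(m2)
  expect_equal(P2[1, ], c(1 / 3, 2 / 3))
  expect_equal(P2[2, ], c(1, 0))
  expect_true(all(abs(rowSums(probs(m2))[m2@supported] - 1) < 1e-9))
  # a symbol with no outgoing pair yields an unsupported all-zero row
  m3 <- transitionProbs(pairCounts(c("A", "A", "B"), c("A", "B", "C")))
  expect_false(m3@supported[3])
  expect_equal(probs(m3)[3, ], rep(0, 3))
})

test_that("independence expectation uses whole-sequence marginals", {
  E <- independenceExpected(c("A", "B", "A", "B"))
  expect_equal(unname(E), matrix(0.75, 2, 2))
  expect_equal(sum(E), 3, tolerance = 1e-9)
  E1 <- independenceExpected(rep("A", 7))
  expect_equal(unname(E1), matrix(6, 1, 1))
})

test_that("chi-squared divergence matches hand computation", {
  O <- pairCounts(c("A", "B", "A", "B"))
  E <- independenceExpected(c("A", "B", "A", "B"))
  expect_equal(chi2Divergence(O, E), 2.75 / 0.75)
  expect_equal(chi2Divergence(E, E), 0)
  expect_equal(chi2Divergence(2 * O, 2 * E), 2 * chi2Divergence(O, E))
  expect_error(chi2Divergence(matrix(1, 2, 2), matrix(0, 2, 2)),
               "undefined cell")
})

test_that("order-1 chi-squared test has the printed degrees of freedom", {
  set.seed(62)
  tok <- sample(c(LETTERS[1:12], "$"), 400, TRUE)
  res <- chi2TestOrder1(tok)
  expect_equal(res@df, 13 * 12)
  expect_gt(pValue(res), 0)
  # strongly order-1 chain at length 6000: overwhelming rejection
  P <- cyclicDominantMatrix(c(LETTERS[1:12], "$"))
  chain <- sampleMarkovSequence(P, 6000, seed = 63)
  expect_lt(pValue(chi2TestOrder1(chain)), 1e-4)
})

test_that("permutation surrogates preserve histograms and rank the truth", {
  # constant sequence: all permutations identical, p = 1
  res <- permutationTestOrder1(rep("A", 30), nSurrogates = 99, seed = 1)
  expect_equal(statistic(res), 0)
  expect_equal(pValue(res), 1)
  # extreme dependence: alternating sequence
  alt <- rep(c("A", "B"), 50)
  expect_lte(pValue(permutationTestOrder1(alt, nSurrogates = 999, seed = 2)),
             0.01)
  # a permutation cannot push the null statistics below zero nor above the
  # maximum the histogram allows; and the observed statistic is invariant to
  # relabeling of positions in the null construction
  set.seed(3)
  tok <- sample(c("A", "B", "C"), 60, TRUE)
  r <- permutationTestOrder1(tok, nSurrogates = 200, seed = 4)
  expect_true(all(r@nullStats >= 0))
  expect_equal(length(r@nullStats), 200L)
  expect_error(permutationTestOrder1(tok, nSurrogates = 0), "invalid")
})

test_that("whittle surrogates conserve pair counts on every draw", {
  expect_equal(whittleSurrogate(c("A", "B", "A", "B"), seed = 1),
               c("A", "B", "A", "B"))  # unique feasible sequence
  set.seed(71)
  for (i in 1:25) {
    tok <- sample(c("A", "B", "C", "$"), sample(10:200, 1), TRUE)
    sur <- whittleSurrogate(tok)
    expect_identical(pairCounts(sur), pairCounts(tok))
    expect_identical(sur[1], tok[1])
    expect_identical(sur[length(sur)], tok[length(tok)])
  }
})

test_that("whittle draws cover exactly the enumerated feasible set", {
  set.seed(72)
  for (rep in 1:12) {
    m <- sample(2:3, 1)
    L <- sample(5:8, 1)
    tok <- sample(LETTERS[1:m], L, TRUE)
    feas <- enumFeasibleSequences(tok)
    draws <- unique(vapply(seq_len(60 * length(feas)), function(i)
      paste(whittleSurrogate(tok), collapse = " "), ""))
    expect_setequal(draws, feas)
  }
})

test_that("whittle sampling is uniform over the feasible set", {
  # fixed small sequences with several feasible trails; goodness of fit of
  # 10,000 draws against the uniform enumeration oracle
  seqs <- list(c("A", "B", "A", "C", "A", "B", "A"),
               c("A", "A", "B", "A", "B", "B", "A"),
               c("C", "B", "A", "B", "C", "A", "B", "C"))
  set.seed(73)
  for (tok in seqs) {
    feas <- enumFeasibleSequences(tok)
    expect_gt(length(feas), 1)
    draws <- vapply(1:10000, function(i)
      paste(whittleSurrogate(tok), collapse = " "), "")
    counts <- table(factor(draws, levels = feas))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("triplet structure has alphabet-cubed entries", {
  set.seed(74)
  tok <- sample(c(LETTERS[1:12], "$"), 500, TRUE)
  arr <- tripletCounts(tok)
  expect_equal(length(arr), 2197L)
  expect_equal(sum(arr), 498L)
})

test_that("order-2 surrogate test is calibrated and powerful", {
  # null: order-1 chains, small calibration run
  P <- cyclicDominantMatrix(LETTERS[1:5], rho = 0.5)
  set.seed(75)
  ps <- vapply(1:30, function(i) {
    tok <- sampleMarkovSequence(P, 1500)
    pValue(surrogateTestOrder2(tok, nSurrogates = 99))
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_lte(mean(ps <= 0.05), 0.2)
  # alternative: genuinely second-order chain
  set.seed(76)
  tok2 <- sampleOrder2Chain(6000, c(LETTERS[1:12], "$"))
  expect_lte(pValue(surrogateTestOrder2(tok2, nSurrogates = 199)), 0.01)
  expect_error(surrogateTestOrder2(tok2, nSurrogates = 0), "invalid")
})

test_that("chi-squared and permutation tests agree in decision", {
  shapes <- LETTERS[1:6]
  set.seed(77)
  agree <- 0
  n <- 40
  for (i in seq_len(n)) {
    # half null (iid), half order-1 chains
    tok <- if (i %% 2 == 0) {
      sample(c(shapes, "$"), 2000, TRUE)
    } else {
      sampleMarkovSequence(cyclicDominantMatrix(c(shapes, "$"), rho = 0.4),
                           2000)
    }
    d1 <- pValue(chi2TestOrder1(tok)) <= 0.01
    d2 <- pValue(permutationTestOrder1(tok, nSurrogates = 499)) <= 0.01
    if (d1 == d2) agree <- agree + 1
  }
  expect_gte(agree / n, 0.9)
})

test_that("estimated transition matrices are consistent", {
  ab <- LETTERS[1:5]
  set.seed(78)
  okCount <- 0
  for (i in 1:40) {
    Q <- randomStochasticMatrix(ab, concentration = 3)
    Q <- (Q + 0.05) / rowSums(Q + 0.05)  # all entries >= 0.05-ish
    tok <- sampleMarkovSequence(Q, 10000)
    est <- probs(transitionProbs(pairCounts(tok, ab)))
    if (max(abs(est - Q)) < 0.05) okCount <- okCount + 1
  }
  expect_gte(okCount / 40, 0.95)
})
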