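test_that("PCA reduction selects a minimal basis reaching the target", {
  # exact 5-dimensional data
  set.seed(41)
  basis5 <- matrix(rnorm(5 * 40), 5, 40)
  W <- matrix(rnorm(60 * 5), 60, 5) %*% basis5
  red <- pcaReduce(W, 0.98)
  expect_lte(red$basis@nSelected, 5L)
  expect_lt(max(abs(red$windows - W)) / max(abs(W)), 1e-8)
  # full basis reproduces the input
  X0 <- W + matrix(rnorm(length(W)), nrow(W)) * 0.01
  full <- pcaReduce(X0, 1.0)
  expect_equal(full$windows, X0, tolerance = 1e-8, ignore_attr = TRUE)
  # known spectrum: n_selected matches the cumulative-ratio count
  set.seed(42)
  sds <- c(5, 3, 2, 1, 0.5, 0.25, 0.1)
  Z <- sapply(sds, function(s) rnorm(400, sd = s))
  Q <- qr.Q(qr(matrix(rnorm(49), 7)))
  X <- Z %*% Q
  red2 <- pcaReduce(X, 0.98)
  ratios <- red2$basis@explainedRatios
  # rotation by the orthogonal Q leaves the spectrum equal to the (nearly
  # uncorrelated) component variances; count from their cumulative ratios
  vz <- sort(apply(Z, 2, var), decreasing = TRUE)
  oracle <- which(cumsum(vz / sum(vz)) >= 0.98)[1]
  expect_equal(red2$basis@nSelected, oracle)
  # minimality: dropping one selected component falls below the target
  if (red2$basis@nSelected > 1)
    expect_lt(sum(ratios[seq_len(red2$basis@nSelected - 1)]), 0.98)
  expect_error(pcaReduce(X[1, , drop = FALSE]), "invalid")
})

test_that("chooseK finds planted cluster counts and flags no structure", {
  set.seed(43)
  centers <- matrix(rnorm(3 * 10, sd = 10), 3, 10)
  blobs <- centers[rep(1:3, each = 40), ] + rnorm(120 * 10)
  expect_equal(chooseK(blobs, 2:8, seed = 1), 3L)
  # 12 planted template classes at low noise
  tpl <- makeTemplates(12, seed = 44)
  pt <- processedTemplates(tpl)
  W <- pt[rep(1:12, each = 25), ] + rnorm(300 * 160, sd = 0.01)
  expect_equal(chooseK(W, 2:15, seed = 2), 12L)
  # single tight blob: minimum candidate, flagged
  blob <- matrix(rnorm(80 * 6), 80, 6)
  expect_message(k1 <- chooseK(blob, 2:5, seed = 3), "no substantial")
  expect_equal(k1, 2L)
  expect_error(chooseK(blobs, integer()), "invalid")
})

test_that("fitDictionary recovers exact and planted prototypes deterministically", {
  pts <- diag(4) * 10
  d <- fitDictionary(pts, 4, seed = 1)
  expect_equal(sort(unname(rowSums(prototypes(d)))), rep(10, 4))
  # planted 5-template data at low noise: high agreement with truth
  tpl <- makeTemplates(5, seed = 45)
  pt <- processedTemplates(tpl)
  truth <- rep(1:5, each = 30)
  W <- pt[truth, ] + rnorm(150 * 160, sd = 0.01)
  d5 <- fitDictionary(W, 5, seed = 2)
  agree <- labelAgreement(labelEvents(W, d5), truth)
  expect_gt(agree, 0.9)
  # determinism
  d5b <- fitDictionary(W, 5, seed = 2)
  expect_identical(prototypes(d5), prototypes(d5b))
  expect_error(fitDictionary(W, 200), "invalid")
})

test_that("labeling matches the brute-force nearest-prototype oracle", {
  tpl <- makeTemplates(6, seed = 46)
  pt <- processedTemplates(tpl)
  d <- new("ShapeDictionary", prototypes = pt, labels = tpl@labels,
           dispersions = pt * 0)
  expect_equal(labelEvents(pt[3, ], d), "C")   # exact prototype
  # exact tie goes to the lowest-index label
  dtie <- new("ShapeDictionary",
              prototypes = rbind(A = c(1, 0, 0), B = c(-1, 0, 0)),
              labels = c("A", "B"), dispersions = matrix(0, 2, 3))
  expect_equal(labelEvents(c(0, 2, 2), dtie), "A")
  set.seed(47)
  W <- pt[sample(1:6, 300, TRUE), ] + rnorm(300 * 160, sd = 0.05)
  lab <- labelEvents(W, d)
  oracle <- apply(W, 1, function(w)
    tpl@labels[which.min(colSums((t(pt) - w)^2))])
  expect_equal(lab, unname(oracle))
  expect_error(labelEvents(W[, 1:10], d), "invalid")
})

test_that("end-to-end dictionary recovery finds the planted classes", {
  # render -> detect -> preprocess -> choose k -> fit, over 10 seeds;
  # the full recovery (k = 12 and prototypes within 3x noise sd per-sample
  # RMS of a template) must hold in at least 8
  good <- 0
  for (seed in 1:10) {
    tpl <- makeTemplates(12, seed = seed)
    # balanced class frequencies isolate dictionary recovery from the
    # class-imbalance effects of a structured chain
    ab <- c(tpl@labels, "$")
    P <- matrix(rep(c(rep(0.75 / 12, 12), 0.25), each = 13), 13, 13,
                dimnames = list(ab, ab))
    tok <- sampleMarkovSequence(P, 700, seed = seed + 200)
    r <- renderRecording(tok, tpl, 0.12, noiseSd = 0.02, seed = seed + 300)
    ev <- preprocessEvents(detectEvents(r$recording), detectionParams())
    d <- buildDictionary(ev, kCandidates = 2:15, seed = seed + 400)
    if (nrow(prototypes(d)) != 12) next
    pt <- processedTemplates(tpl)
    rms <- apply(prototypes(d), 1, function(p)
      min(sqrt(colMeans((t(pt) - p)^2))))
    if (max(rms) < 3 * 0.02) good <- good + 1
  }
  expect_gte(good, 8)
})
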