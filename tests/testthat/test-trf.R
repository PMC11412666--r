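# Ridge TRF machinery: embedding, solving, regularization search,
# prediction, scoring, shuffle significance, splits.

test_that("delay embedding shifts columns as specified", {
  x <- matrix(rnorm(30), ncol = 1)
  expect_equal(delayEmbed(x, 0L), x, ignore_attr = TRUE)

  imp <- matrix(0, 30, 1); imp[11, 1] <- 1
  D <- delayEmbed(imp, 0:3)
  for (l in 0:3) expect_equal(which(D[, l + 1] == 1), 11 + l)

  set.seed(21)
  x3 <- matrix(rnorm(40 * 3), 40)
  lags <- 0:4
  D3 <- delayEmbed(x3, lags)
  loopOracle <- matrix(0, 40, 15)
  for (f in 1:3) for (li in seq_along(lags)) for (t in 1:40) {
    src <- t - lags[li]
    if (src >= 1) loopOracle[t, (f - 1) * 5 + li] <- x3[src, f]
  }
  expect_equal(unname(D3), loopOracle)

  expect_error(delayEmbed(matrix(0, 0, 1), 0:3), "empty")
})

test_that("ridge solutions match closed forms and independent solves", {
  set.seed(22)
  # orthonormal design, lambda = 0: weights are S'Y
  q <- qr.Q(qr(matrix(rnorm(50 * 5), 50)))
  y <- matrix(rnorm(50 * 2), 50)
  expect_equal(ridgeFit(q, y, 0), crossprod(q, y), tolerance = 1e-10)

  # extreme shrinkage
  s <- matrix(rnorm(40 * 4), 40)
  expect_lt(max(abs(ridgeFit(s, y[1:40, ], 1e12))), 1e-6)

  # 30 random instances vs brute-force normal equations
  for (i in 1:30) {
    n <- sample(15:40, 1); p <- sample(3:10, 1)
    S <- matrix(rnorm(n * p), n)
    Y <- matrix(rnorm(n * 2), n)
    lam <- exp(runif(1, 0, 6))
    oracle <- solve(t(S) %*% S + lam * diag(p)) %*% t(S) %*% Y
    expect_lt(max(abs(ridgeFit(S, Y, lam) - oracle)), 1e-8)
  }

  # rank-deficient with lambda = 0 advises regularization
  Sdef <- cbind(1:20, 1:20)
  expect_error(ridgeFit(Sdef, matrix(rnorm(20)), 0), "lambda > 0")
})

test_that("per-channel lambdas solve each channel at its own penalty", {
  set.seed(23)
  S <- matrix(rnorm(60 * 6), 60)
  Y <- matrix(rnorm(60 * 3), 60)
  lam <- c(1, 100, 1)
  W <- ridgeFit(S, Y, lam)
  for (ch in 1:3)
    expect_equal(W[, ch], ridgeFit(S, Y[, ch, drop = FALSE], lam[ch])[, 1],
                 tolerance = 1e-10)
})

test_that("cv lambda selects small penalties on clean data and recovers", {
  set.seed(24)
  nT <- 60 * 128
  x <- matrix(rnorm(nT * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  lags <- 0:10
  K <- array(rnorm(2 * 11 * 3, 0, 0.5), c(2, 11, 3))
  Y <- delayEmbed(x, lags) %*% matrix(aperm(K, c(2, 1, 3)), nrow = 22)
  Y <- Y + 0.01 * matrix(rnorm(length(Y)), nrow(Y))
  grid <- logspace(1e2, 1e8, 15)
  lam <- cvLambda(x, Y, lags, grid, nIter = 8, seed = 1)
  expect_true(all(lam <= grid[8]))
  m <- trainTRF(x, Y, lags, lambda = as.numeric(lam))
  w <- nativeWeights(m)
  rec <- sapply(1:3, function(n) cor(as.vector(w[, , n]), as.vector(K[, , n])))
  expect_true(all(rec > 0.95))

  # grid of length 1 returns that lambda everywhere
  one <- cvLambda(x, Y, lags, lambdaGrid = 500, nIter = 3, seed = 2)
  expect_true(all(one == 500))
})

test_that("pure-noise responses evaluate near zero on held-out data", {
  set.seed(25)
  x <- matrix(rnorm(50 * 128 * 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  Y <- matrix(rnorm(nrow(x) * 2), ncol = 2)
  trainIdx <- 1:5120
  m <- trainTRF(x[trainIdx, ], Y[trainIdx, ], lags = 0:10,
                lambdaGrid = logspace(1e2, 1e8, 5), nIter = 5, seed = 3)
  r <- scoreChannels(predictResponse(m, x[-trainIdx, ]), Y[-trainIdx, ])
  expect_lt(mean(abs(r)), 2 / sqrt(nrow(Y) - 5120))
})

test_that("prediction follows the lagged linear form", {
  set.seed(26)
  x <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "f"))

  m0 <- trainTRF(x, matrix(rnorm(50), ncol = 1), lags = 0:3, lambda = 1,
                 standardize = FALSE)
  m0@weights[] <- 0
  expect_equal(max(abs(predictResponse(m0, x))), 0)

  m1 <- m0
  m1@weights[1, 3, 1] <- 2  # single feature, lag 2, weight 2
  pred <- predictResponse(m1, x)[, 1]
  expect_equal(pred[3:50], 2 * x[1:48, 1])

  # random model equals design %*% flattened weights computed independently
  x2 <- matrix(rnorm(60 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m2 <- trainTRF(x2, matrix(rnorm(60 * 2), ncol = 2), lags = 0:4,
                 lambda = 1, standardize = FALSE)
  manual <- delayEmbed(x2, 0:4) %*%
    matrix(aperm(weights(m2), c(2, 1, 3)), nrow = 10)
  expect_equal(unname(predictResponse(m2, x2)), unname(manual))

  colnames(x2) <- c("a", "zz")
  expect_error(predictResponse(m2, x2), "feature names")
})

test_that("scoring matches the textbook correlation and handles edge cases", {
  set.seed(27)
  a <- matrix(rnorm(200 * 2), 200)
  expect_equal(scoreChannels(a, a), c(1, 1))
  expect_equal(scoreChannels(a, -a), c(-1, -1))

  b <- matrix(rnorm(200 * 2), 200)
  oracle <- sapply(1:2, function(i) {
    num <- sum((a[, i] - mean(a[, i])) * (b[, i] - mean(b[, i])))
    num / sqrt(sum((a[, i] - mean(a[, i]))^2) * sum((b[, i] - mean(b[, i]))^2))
  })
  expect_equal(scoreChannels(a, b), oracle, tolerance = 1e-12)

  flat <- cbind(a[, 1], rep(1, 200))
  expect_warning(r <- scoreChannels(a, flat), "zero-variance")
  expect_equal(r[2], 0)
})

test_that("training-set fit quality is non-increasing in lambda", {
  set.seed(28)
  x <- matrix(rnorm(2000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  K <- array(rnorm(2 * 6 * 2), c(2, 6, 2))
  Y <- delayEmbed(x, 0:5) %*% matrix(aperm(K, c(2, 1, 3)), nrow = 12)
  Y <- Y + 0.5 * matrix(rnorm(length(Y)), nrow(Y))
  rs <- sapply(c(1, 1e2, 1e4, 1e6), function(lam) {
    m <- trainTRF(x, Y, 0:5, lambda = lam)
    mean(scoreChannels(predictResponse(m, x), Y))
  })
  expect_true(all(diff(rs) <= 1e-10))
})

test_that("in-span responses are reproduced exactly as lambda -> 0", {
  set.seed(29)
  x <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "f"))
  S <- delayEmbed(x, 0:4)
  Y <- S %*% matrix(rnorm(5), ncol = 1)
  m <- trainTRF(x, Y, 0:4, lambda = 1e-10, standardize = FALSE)
  expect_lt(max(abs(predictResponse(m, x) - Y)), 1e-6)
})

test_that("shuffle test flags driven channels and caps p at 1", {
  set.seed(30)
  nT <- 90 * 128
  x <- matrix(rnorm(nT), ncol = 1, dimnames = list(NULL, "f"))
  k <- exp(-(0:10 - 4)^2 / 8)
  sig <- delayEmbed(x, 0:10) %*% matrix(k, ncol = 1)
  Y <- cbind(driven = sig + 0.3 * rnorm(nT), null = rnorm(nT))
  tr <- 1:(70 * 128)
  res <- shuffleTest(x[tr, , drop = FALSE], Y[tr, ], x[-tr, , drop = FALSE],
                     Y[-tr, ], lags = 0:10, lambda = 100, nShuffles = 50,
                     seed = 4)
  p <- pValues(res)
  expect_lte(p[1], 0.02)  # add-one estimator floor at 1/51
  expect_gt(p[2], 0.05)

  # worst case: a good model scored against a sign-flipped test response
  # sits below every shuffled model, so p is at its ceiling
  resBad <- shuffleTest(x[tr, , drop = FALSE],
                        cbind(sig[tr, 1]),
                        x[-tr, , drop = FALSE],
                        cbind(-sig[-tr, 1]),
                        lags = 0:10, lambda = 100, nShuffles = 20, seed = 5)
  expect_gte(pValues(resBad)[1], 20 / 21)

  expect_error(shuffleTest(x[tr, , drop = FALSE], Y[tr, ],
                           x[-tr, , drop = FALSE], Y[-tr, ],
                           lambda = 100, nShuffles = 0), "nShuffles")
})

test_that("the shared-design driver matches the single-model path", {
  set.seed(64)
  x <- matrix(rnorm(4000 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  K <- array(rnorm(3 * 9 * 4, 0, 0.4), c(3, 9, 4))
  Y <- delayEmbed(x, 0:8) %*% matrix(aperm(K, c(2, 1, 3)), nrow = 27)
  Y <- Y + 0.4 * matrix(rnorm(length(Y)), nrow(Y))
  tr <- 1:3000
  grid <- logspace(1e2, 1e6, 5)
  res <- runConditionAnalysis(x[tr, ], list(uni = Y[tr, ]), x[-tr, ],
                              Y[-tr, ], lags = 0:8, lambdaGrid = grid,
                              nIter = 6, seed = 3)
  lamRef <- cvLambda(x[tr, ], Y[tr, ], 0:8, grid, nIter = 6, seed = 3)
  expect_equal(as.numeric(res$lambda$uni), as.numeric(lamRef))
  mRef <- trainTRF(x[tr, ], Y[tr, ], 0:8, lambda = as.numeric(lamRef))
  expect_lt(max(abs(nativeWeights(res$models$uni) - nativeWeights(mRef))),
            1e-10)
  evRef <- evaluateTRF(mRef, x[-tr, ], Y[-tr, ])
  expect_equal(rValues(res$evals$uni), rValues(evRef), tolerance = 1e-12)
})

test_that("trailer splits are deterministic and validated", {
  ids <- sprintf("tr%02d", 1:8)
  sp <- splitByTrailer(ids, c("tr07", "tr08"))
  expect_equal(sp$train, sprintf("tr%02d", 1:6))
  expect_equal(sp$test, c("tr07", "tr08"))
  expect_error(splitByTrailer(ids, character(0)), "empty")
  expect_error(splitByTrailer(ids, ids), "training set is empty")
  expect_error(splitByTrailer(ids, "tr99"), "unknown")
})
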