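# Cross-condition analyses: cross-prediction, within/cross regression,
# weight correlation topographies, EEG correlation, ROI summaries.

test_that("ROI assignment follows 10-20 prefixes", {
  roi <- assignROI(c("Fp1", "AF3", "F5", "FCz", "Cz", "CP2", "Pz", "POz",
                     "Oz", "T7", "FT8", "TP10", "Iz"))
  expect_equal(unname(roi),
               c("frontal", "frontal", "frontal", "central", "central",
                 "parietal", "parietal", "occipital", "occipital",
                 "temporal", "temporal", "temporal", "occipital"))
  expect_equal(unname(assignROI("T7", overrides = c(T7 = "central"))),
               "central")
  expect_true(all(defaultROIMap() %in%
    c("frontal", "central", "parietal", "occipital", "temporal")))
})

test_that("cross-prediction enforces the feature family", {
  set.seed(31)
  x <- matrix(rnorm(300 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  m <- trainTRF(x, matrix(rnorm(300 * 2), ncol = 2), lags = 0:3, lambda = 10)
  wrong <- FeatureStream(x, c("a", "c"), "auditory")
  expect_error(crossPredict(m, wrong, matrix(rnorm(300 * 2), ncol = 2)),
               "family")

  m0 <- m; m0@weights[] <- 0
  expect_warning(
    ev <- crossPredict(m0, FeatureStream(x, c("a", "b"), "auditory"),
                       matrix(rnorm(300 * 2), ncol = 2)),
    "zero-variance")
  expect_equal(rValues(ev), c(0, 0))
})

test_that("within/cross table recovers exact linear relations", {
  rec <- data.frame(subject = "S1", channel = sprintf("ch%02d", 1:40),
                    roi = "central",
                    r_within = seq(0.01, 0.4, length.out = 40),
                    model_family = "auditory")
  rec$r_cross <- rec$r_within
  out <- withinVsCrossTable(rec)
  expect_equal(out$regression$slope, 1, tolerance = 1e-12)
  expect_equal(out$regression$intercept, 0, tolerance = 1e-12)
  expect_equal(out$regression$r, 1, tolerance = 1e-12)

  rec$r_cross <- rec$r_within - 0.05
  out2 <- withinVsCrossTable(rec)
  expect_equal(out2$regression$slope, 1, tolerance = 1e-12)
  expect_equal(out2$regression$intercept, -0.05, tolerance = 1e-12)

  set.seed(32)
  rec$r_within <- rnorm(40, 0.2, 0.1)
  rec$r_cross <- 0.8 * rec$r_within + rnorm(40, 0, 0.02)
  out3 <- withinVsCrossTable(rec)
  ls <- stats::lsfit(rec$r_within, rec$r_cross)
  expect_equal(out3$regression$slope, unname(ls$coefficients[2]),
               tolerance = 1e-10)
  expect_equal(out3$regression$intercept, unname(ls$coefficients[1]),
               tolerance = 1e-10)

  expect_error(
    withinVsCrossTable(rec[, setdiff(names(rec), "r_within")]), "columns")
})

test_that("weight correlation maps are exact for copies and symmetric", {
  set.seed(33)
  x <- matrix(rnorm(2000 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  Y <- matrix(rnorm(2000 * 3), ncol = 3)
  m1 <- trainTRF(x, Y, lags = 0:5, lambda = 10)
  expect_equal(unname(weightCorrelationMap(m1, m1)), rep(1, 3))

  mNeg <- m1; mNeg@weights <- -m1@weights
  expect_equal(unname(weightCorrelationMap(m1, mNeg)), rep(-1, 3))

  m2 <- trainTRF(x, Y + matrix(rnorm(length(Y)), nrow(Y)), lags = 0:5,
                 lambda = 10)
  expect_equal(weightCorrelationMap(m1, m2), weightCorrelationMap(m2, m1))

  m3 <- trainTRF(x, Y, lags = 0:4, lambda = 10)
  expect_error(weightCorrelationMap(m1, m3), "delay grids")
})

test_that("models fit on independent data from shared kernels correlate", {
  set.seed(34)
  lags <- 0:15
  K <- array(rnorm(2 * 16 * 6, 0, 0.4), c(2, 16, 6))
  fit <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 128 * 2), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
    sig <- delayEmbed(x, lags) %*% matrix(aperm(K, c(2, 1, 3)), nrow = 32)
    Y <- sig + 0.1 * matrix(rnorm(length(sig)), nrow(sig))  # high SNR
    trainTRF(x, Y, lags, lambda = 100)
  }
  r <- weightCorrelationMap(fit(101), fit(202))
  expect_gt(mean(r), 0.8)
})

test_that("inter-condition EEG correlation behaves and ranks shared channels", {
  set.seed(35)
  base <- matrix(rnorm(4 * 2000), 4)
  labs <- c("Oz", "POz", "Fz", "Cz")
  e1 <- EEGEpoch(base, labs, "AV", trailerId = "tr01")
  expect_equal(eegConditionCorrelation(e1, e1)$r, rep(1, 4))

  eNoise <- EEGEpoch(matrix(rnorm(4 * 2000), 4), labs, "V",
                     trailerId = "tr01")
  expect_lt(max(abs(eegConditionCorrelation(e1, eNoise)$r)),
            2 / sqrt(2000))

  # AV and V sharing the visual component at visual channels
  vis <- matrix(rnorm(4 * 2000), 4) * c(1, 1, 0.05, 0.05)
  av <- EEGEpoch(base * 0.5 + vis, labs, "AV", trailerId = "tr02")
  vo <- EEGEpoch(matrix(rnorm(4 * 2000), 4) * 0.5 + vis, labs, "V",
                 trailerId = "tr02")
  cc <- eegConditionCorrelation(av, vo)
  expect_true(all(rank(-cc$r)[1:2] <= 2))
  expect_equal(range(cc$rNormalized), c(0, 1))

  e3 <- EEGEpoch(base, labs, "A", trailerId = "tr09")
  expect_error(eegConditionCorrelation(e1, e3), "different trailers")
})

test_that("ROI summary aggregates and its permutation test calibrates", {
  roimap <- defaultROIMap()
  ch <- names(roimap)
  set.seed(36)
  mkRecords <- function(shift) {
    do.call(rbind, lapply(sprintf("S%02d", 1:14), function(s) {
      base <- rnorm(length(ch), 0.1, 0.05)
      rbind(data.frame(subject = s, condition = "A", channel = ch,
                       r = base),
            data.frame(subject = s, condition = "B", channel = ch,
                       r = base + rnorm(length(ch), shift, 0.02)))
    }))
  }
  nullRes <- roiSummary(mkRecords(0), roimap, nPermutations = 2000, seed = 1)
  expect_gt(nullRes$comparisons$p, 0.05)
  expect_setequal(unique(nullRes$summary$roi),
                  c("frontal", "central", "parietal", "occipital",
                    "temporal"))

  effRes <- roiSummary(mkRecords(0.05), roimap, nPermutations = 2000,
                       seed = 1)
  expect_lte(effRes$comparisons$p, 0.001)

  single <- mkRecords(0)
  single <- single[single$subject == "S01", ]
  expect_error(roiSummary(single, roimap), "2 subjects")
})
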