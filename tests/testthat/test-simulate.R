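# Synthetic-data generator: feature structure, EEG construction, dataset
# assembly, toy videos.

test_that("simulated features have the contracted structure", {
  fs <- simulateFeatures(600, seed = 41)
  m <- streamData(fs)
  expect_equal(ncol(m), 27)
  expect_equal(sum(modality(fs) == "auditory"), 16)

  # binary phonological columns
  expect_true(all(m[, 1:14] %in% c(0, 1)))

  # auditory and visual blocks mutually uncorrelated
  cc <- cor(m[, modality(fs) == "auditory"],
            m[, modality(fs) == "visual"])
  expect_lt(mean(abs(cc)), 0.05)

  # phoneme onset count within 3 sd of the renewal expectation
  nOnsets <- sum(apply(m[, 1:14], 1, max))
  rate <- 6; refractory <- 0.06
  expShape <- 1 / rate - refractory
  sdCount <- sqrt(600 / (1 / rate)) * (expShape / (1 / rate))
  expect_lt(abs(nOnsets - rate * 600), 3 * sdCount + 10)

  # pitch stays within the advertised range
  expect_true(all(m[, "pitch"] >= 0 & m[, "pitch"] <= 300))
  expect_true(all(m[, "envelope"] >= 0))
})

test_that("bundle structure shows in phonological correlations", {
  fs <- simulateFeatures(300, seed = 42)
  m <- streamData(fs)
  cc <- cor(m[, 1:14])
  # sonorant/voiced co-occur (every vowel carries both); sonorant/obstruent
  # never co-occur
  expect_gt(cc["sonorant", "voiced"], cc["sonorant", "obstruent"])
  expect_lt(cc["sonorant", "obstruent"], 0)
})

test_that("simulation is reproducible and condition-additive", {
  a <- simulateFeatures(30, seed = 43)
  b <- simulateFeatures(30, seed = 43)
  expect_identical(streamData(a), streamData(b))

  gt <- makeGroundTruth(snrDb = 0, seed = 44)
  eAV <- simulateEEG(a, gt, "AV", noise = FALSE)
  eA <- simulateEEG(a, gt, "A", noise = FALSE)
  eV <- simulateEEG(a, gt, "V", noise = FALSE)
  expect_equal(epochData(eAV), epochData(eA) + epochData(eV),
               tolerance = 1e-12)

  ds1 <- makeDataset(3, duration = 30, seed = 45)
  ds2 <- makeDataset(3, duration = 30, seed = 45)
  expect_identical(epochData(ds1@eeg$tr01$AV), epochData(ds2@eeg$tr01$AV))
  expect_identical(ds1@testTrailers, c("tr02", "tr03"))
})

test_that("unimodal conditions carry no trace of the other modality", {
  fs <- simulateFeatures(120, seed = 46)
  gt <- makeGroundTruth(snrDb = 20, seed = 47)
  eA <- simulateEEG(fs, gt, "A", seed = 48)
  visStim <- featureFamily(fs, "visual")
  tr <- 1:(100 * 128)
  m <- trainTRF(FeatureStream(streamData(visStim)[tr, ],
                              featureNames(visStim), "visual"),
                t(epochData(eA))[tr, ], lags = 0:20, lambda = 1e3)
  heldS <- FeatureStream(streamData(visStim)[-tr, ],
                         featureNames(visStim), "visual")
  r <- scoreChannels(predictResponse(m, heldS), t(epochData(eA))[-tr, ])
  expect_lt(median(abs(r)), 2 / sqrt(20 * 128))
})

test_that("zero gains produce pure noise with null test performance", {
  fs <- simulateFeatures(60, seed = 49)
  gt <- makeGroundTruth(snrDb = 0, seed = 50)
  gt@kernels[] <- 0
  e <- simulateEEG(fs, gt, "AV", seed = 51)
  tr <- 1:(45 * 128)
  sf <- featureFamily(fs, "auditory")
  m <- trainTRF(FeatureStream(streamData(sf)[tr, ], featureNames(sf),
                              "auditory"),
                t(epochData(e))[tr, ], lags = 0:15, lambda = 1e4)
  # near-zero weights can give constant predictions; the zero-variance
  # convention reports r = 0 with a warning
  r <- suppressWarnings(scoreChannels(predictResponse(m,
    FeatureStream(streamData(sf)[-tr, ], featureNames(sf), "auditory")),
    t(epochData(e))[-tr, ]))
  expect_lt(mean(abs(r)), 2 / sqrt(15 * 128))
})

test_that("kernel recovery improves monotonically with SNR", {
  fs <- simulateFeatures(150, seed = 52)
  sf <- featureFamily(fs, "auditory")
  errs <- sapply(c(-10, 0, 10, 20), function(snr) {
    gt <- makeGroundTruth(snrDb = snr, seed = 53)
    e <- simulateEEG(fs, gt, "A", seed = 54)
    m <- trainTRF(sf, t(epochData(e)), lambda = 3e3)
    w <- nativeWeights(m)
    keep <- gt@modality == "auditory"
    dr <- match(drivenChannels(gt, "auditory"), gt@channelLabels)
    1 - median(sapply(dr, function(n)
      cor(as.vector(w[, , n]), as.vector(gt@kernels[keep, , n]))))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("high-SNR fits recover kernels almost perfectly", {
  fs <- simulateFeatures(150, seed = 55)
  gt <- makeGroundTruth(snrDb = 60, seed = 56)
  e <- simulateEEG(fs, gt, "A", seed = 57)
  sf <- featureFamily(fs, "auditory")
  m <- trainTRF(sf, t(epochData(e)), lambda = 1e-2)
  w <- nativeWeights(m)
  keep <- gt@modality == "auditory"
  dr <- match(drivenChannels(gt, "auditory"), gt@channelLabels)
  rc <- sapply(dr, function(n)
    cor(as.vector(w[, , n]), as.vector(gt@kernels[keep, , n])))
  expect_gt(mean(rc), 0.99)
})

test_that("toy videos are deterministic and spectrally correct", {
  blank <- makeToyVideo("blank", nFrames = 2)
  expect_equal(dim(blank), c(720, 1280, 3, 2))
  expect_equal(max(abs(blank)), 0)

  n1 <- makeToyVideo("noise", nFrames = 2, seed = 7)
  n2 <- makeToyVideo("noise", nFrames = 2, seed = 7)
  expect_identical(n1, n2)

  # a 1.33 Hz grating's pixel time series peaks at 1.33 Hz
  g <- makeToyVideo("drifting_grating", nFrames = 18, temporalFreq = 4 / 3)
  px <- g[360, 640, 1, ]
  rm(g); gc(FALSE)
  spec <- Mod(fft(px - mean(px)))[2:9]
  expect_equal(which.max(spec), 1)  # bin 1 = 24/18 = 1.33 Hz
  expect_error(makeToyVideo("drifting_grating", nFrames = 0), "nFrames")
})
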