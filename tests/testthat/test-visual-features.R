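# Visual pipeline: frame preprocessing, Gabor bank construction, motion
# energy, PCA reduction, scene cuts.

test_that("frame preprocessing pads, resizes, and extracts luminance", {
  black <- array(0, c(720, 1280, 3, 2))
  out <- preprocessFrames(black)
  expect_equal(dim(out), c(96, 96, 2))
  expect_equal(max(abs(out)), 0)

  white <- array(1, c(720, 1280, 3))
  w <- preprocessFrames(white)[, , 1]
  # padded rows (top ~21 rows of 96) stay black, interior is max luminance
  expect_lt(max(w[1:18, ]), 0.05)
  expect_gt(min(w[30:66, ]), 0.95)

  gray <- array(0.5, c(720, 1280, 3))
  g <- preprocessFrames(gray)[, , 1]
  # independent sRGB -> L* oracle for 0.5 gray
  lin <- ((0.5 + 0.055) / 1.055)^2.4
  Lstar <- (116 * lin^(1 / 3) - 16) / 100
  expect_equal(mean(g[40:60, 40:60]), Lstar, tolerance = 1e-3)

  expect_error(preprocessFrames(array(0, c(96, 96, 3))), "720 x 1280")
})

test_that("default Gabor bank structure follows the stated grid", {
  b <- buildGaborBank()
  ft <- filterTable(b)
  # one pure-Gaussian zero-spatial-frequency filter
  expect_equal(sum(ft$sf == 0), 1)
  # static filters appear at four orientations only
  expect_setequal(unique(ft$dir[ft$tf == 0 & ft$sf > 0]), c(0, 45, 90, 135))
  # motion filters at eight directions
  expect_setequal(unique(ft$dir[ft$tf > 0]), seq(0, 315, 45))
  # adjacent same-parameter filters separated by 4 spatial SDs
  sub <- ft[ft$sf == 24 & ft$tf == 0 & ft$dir == 0, ]
  cx <- sort(unique(sub$cx))
  expect_equal(diff(cx), rep(4 * sub$sigmaS[1], length(cx) - 1))
  # deterministic
  expect_identical(filterTable(buildGaborBank()), ft)
})

test_that("bank filter count matches an independent tiling enumeration", {
  enumerate <- function(sfs, cyclesPerSD = 0.6, cap = 0.3, spacing = 4,
                        dirsMotion = 8, dirsStatic = 4) {
    total <- 0
    for (sf in sfs) {
      sigma <- min(cyclesPerSD / sf, cap)
      n <- max(1, ceiling(1 / (spacing * sigma) - 1e-9))
      total <- total + n^2 * (2 * dirsMotion + dirsStatic)
    }
    total + 1
  }
  expect_equal(nFilters(buildGaborBank()),
               enumerate(c(1.5, 3, 6, 12, 24)))

  # single spatial frequency, one orientation, static only
  b1 <- buildGaborBank(spatialFreqs = 6, temporalFreqs = 0,
                       staticDirections = 0)
  sigma <- 0.6 / 6
  n <- ceiling(1 / (4 * sigma))
  expect_equal(nFilters(b1), n^2 + 1)

  # zero-spatial-frequency-only bank
  expect_equal(nFilters(buildGaborBank(spatialFreqs = numeric(0))), 1)
})

test_that("counting phases separately doubles every quadrature pair", {
  a <- buildGaborBank(spatialFreqs = c(6, 12))
  b <- buildGaborBank(spatialFreqs = c(6, 12), countPhases = TRUE)
  nGauss <- 1
  expect_equal(nFilters(b), 2 * (nFilters(a) - nGauss) + nGauss)
})

test_that("motion energy is zero for a blank movie", {
  bank <- buildGaborBank(spatialFreqs = c(6, 12))
  blank <- array(0.5, c(96, 96, 12))
  E <- streamData(motionEnergy(blank, bank))
  ft <- filterTable(bank)
  expect_lt(max(E[, ft$sf > 0]), 1e-8)
})

test_that("motion energy is direction selective and quadrature invariant", {
  bank <- buildGaborBank(spatialFreqs = 6, temporalFreqs = 4 / 3)
  ft <- filterTable(bank)
  mov <- gratingMovie(36, 6, 0, 4 / 3)
  E <- colMeans(streamData(motionEnergy(mov, bank)))
  matched <- which(ft$sf == 6 & ft$dir == 0)
  opposite <- which(ft$sf == 6 & ft$dir == 180)
  expect_gt(mean(E[matched]), mean(E[opposite]))

  # shifting the grating's spatial phase leaves energy unchanged within 2%
  movShift <- gratingMovie(36, 6, 0, 4 / 3, spatialPhase = pi / 3)
  E2 <- colMeans(streamData(motionEnergy(movShift, bank)))
  expect_lt(max(abs(E2[matched] - E[matched]) / E[matched]), 0.02)
})

test_that("temporal frequency tuning separates 1.33 from 2.667 Hz", {
  bank <- buildGaborBank(spatialFreqs = 6)
  ft <- filterTable(bank)
  mov <- gratingMovie(48, 6, 90, 4 / 3)
  E <- colMeans(streamData(motionEnergy(mov, bank)))
  slow <- which(abs(ft$tf - 4 / 3) < 1e-9 & ft$dir == 90)
  fast <- which(abs(ft$tf - 8 / 3) < 1e-9 & ft$dir == 90)
  expect_gt(mean(E[slow]) / mean(E[fast]), 1)
})

test_that("motion energy ignores global luminance offsets", {
  bank <- buildGaborBank(spatialFreqs = 12, temporalFreqs = 4 / 3)
  set.seed(11)
  mov <- array(runif(96 * 96 * 12, 0.2, 0.8), c(96, 96, 12))
  e1 <- streamData(motionEnergy(mov, bank))
  e2 <- streamData(motionEnergy(mov + 0.1, bank))
  ft <- filterTable(bank)
  expect_lt(max(abs(e1[, ft$sf > 0] - e2[, ft$sf > 0])), 1e-6)
})

test_that("PCA reduction matches eigendecomposition and is orthogonal", {
  set.seed(12)
  base <- matrix(rnorm(400 * 2), 400)
  lowRank <- base %*% matrix(rnorm(2 * 30), 2)
  fsLow <- FeatureStream(lowRank, paste0("g", 1:30), "visual")
  pr <- pcaReduce(fsLow, k = 10)
  expect_lt(sum(pr$projection$sdev[3:10]^2), 1e-10)

  x <- matrix(rnorm(300 * 20), 300)
  fs <- FeatureStream(x, paste0("g", 1:20), "visual")
  p <- pcaReduce(fs, k = 5)
  sc <- streamData(p$stream)
  gram <- crossprod(sc)
  offdiag <- gram - diag(diag(gram))
  expect_lt(max(abs(offdiag)) / max(diag(gram)), 1e-8)

  # reconstruction error equals the independent eigendecomposition residual
  xc <- scale(x, scale = FALSE)
  eg <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  resid <- sum(eg$values[6:20])
  recon <- sc %*% t(p$projection$rotation)
  err <- sum((xc - recon)^2) / (nrow(x) - 1)
  expect_equal(err, resid, tolerance = 1e-8)

  # projection reused verbatim on new data
  x2 <- matrix(rnorm(50 * 20), 50)
  proj2 <- applyPcaProjection(FeatureStream(x2, paste0("g", 1:20), "visual"),
                              p$projection)
  manual <- sweep(x2, 2, p$projection$center) %*% p$projection$rotation
  expect_equal(unname(streamData(proj2)), unname(manual))

  expect_error(pcaReduce(fs, k = 25), "exceeds")
})

test_that("scene-cut vectors place impulses at the nearest samples", {
  annot <- AnnotationTrack(list(
    scene = data.frame(start = c(1, 2), end = c(1, 2), label = "cut")))
  v <- streamData(sceneCutVector(annot, duration = 3))[, 1]
  expect_equal(which(v == 1), c(129, 257))  # samples 128 and 256, 0-based

  none <- AnnotationTrack(list(
    scene = data.frame(start = numeric(0), end = numeric(0),
                       label = character(0))))
  expect_equal(sum(streamData(sceneCutVector(none, 3))), 0)

  set.seed(13)
  cuts <- sort(runif(50, 0, 99))
  cuts <- cuts + seq(0, 4.9, by = 0.1)  # keep nearest samples distinct
  a2 <- AnnotationTrack(list(
    scene = data.frame(start = cuts, end = cuts, label = "cut")))
  expect_equal(sum(streamData(sceneCutVector(a2, 110))), 50)

  expect_error(sceneCutVector(annot, duration = 1.5), "beyond")
})
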