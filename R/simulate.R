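# Synthetic-data generator: feature streams with speech-like statistical
# structure, EEG as kernel-convolved feature sums plus 1/f noise, under
# AV / A / V conditions with topographically structured gains.

.AUD_FEATURES <- c(.PHONO_FEATURES, "envelope", "pitch")
.VIS_FEATURES <- c(paste0("gaborPC", 1:10), "scene_cut")
.SIM_FEATURES <- c(.AUD_FEATURES, .VIS_FEATURES)
.SIM_MODALITY <- c(rep("auditory", 16), rep("visual", 11))

# Nominal scales (typical SDs) of the simulated feature streams; true kernel
# amplitudes are divided by these so every feature drives EEG variance of the
# same order, as scalp responses do (a phoneme onset and an envelope swing
# both produce microvolt-scale deflections).
.SIM_FEATURE_SCALE <- c(
  sonorant = 0.18, obstruent = 0.12, voiced = 0.19, nasal = 0.06,
  syllabic = 0.16, fricative = 0.10, plosive = 0.08, labial = 0.07,
  coronal = 0.10, dorsal = 0.06, front = 0.11, back = 0.12, high = 0.10,
  low = 0.09, envelope = 1.15, pitch = 86,
  gaborPC1 = 1, gaborPC2 = 0.71, gaborPC3 = 0.58, gaborPC4 = 0.5,
  gaborPC5 = 0.45, gaborPC6 = 0.41, gaborPC7 = 0.38, gaborPC8 = 0.35,
  gaborPC9 = 0.33, gaborPC10 = 0.32, scene_cut = 0.06)

#' Simulate a feature stream with known structure
#'
#' Phoneme onsets are drawn as a renewal process (exponential waiting times
#' plus a 60 ms refractory period); each event samples an ARPAbet phoneme and
#' sets 1s in the 14 binary phonological columns it carries, inducing the
#' within-modality co-occurrence structure of real speech. The envelope is a
#' phoneme-driven smoothed positive process; pitch is a band-limited random
#' walk in [50, 300] Hz gated by voiced events; the 10 visual principal
#' components are independent Gaussian processes (length scale 200 ms,
#' decreasing variance); scene cuts are Poisson impulses. Auditory and visual
#' blocks are mutually independent by construction.
#'
#' @param duration seconds (>= 30).
#' @param seed RNG seed.
#' @param phonemeRate phoneme events per second.
#' @param cutRate scene cuts per second.
#' @param rate output rate (128).
#' @return a 27-column \linkS4class{FeatureStream} (16 auditory, 11 visual).
#' @export
simulateFeatures <- function(duration, seed = 0, phonemeRate = 6,
                             cutRate = 0.4, rate = 128) {
  if (duration < 30) stop("simulateFeatures expects duration >= 30 s")
  if (phonemeRate <= 0 || cutRate < 0) stop("invalid event rates")
  refractory <- 0.06
  if (1 / phonemeRate <= refractory)
    stop("phonemeRate too high for the 60 ms refractory period")
  set.seed(seed)
  nSamp <- round(duration * rate)
  fmap <- defaultPhonemeFeatureMap()
  phonemes <- names(fmap)
  # vowels are more frequent than any single consonant, as in speech
  wts <- ifelse(vapply(fmap, function(f) "syllabic" %in% f, TRUE), 2, 1)
  # phoneme onsets: renewal process
  tEv <- numeric(0); t <- 0
  repeat {
    t <- t + refractory + stats::rexp(1, 1 / (1 / phonemeRate - refractory))
    if (t >= duration) break
    tEv <- c(tEv, t)
  }
  lab <- sample(phonemes, length(tEv), replace = TRUE, prob = wts)
  phono <- matrix(0, nSamp, 14, dimnames = list(NULL, .PHONO_FEATURES))
  idx <- pmin(nSamp, round(tEv * rate) + 1L)
  for (k in seq_along(tEv)) phono[idx[k], fmap[[lab[k]]]] <- 1
  # envelope: speech part (events convolved with an alpha kernel) plus an
  # independent music/background energy process, so the envelope is not a
  # linear function of the phoneme train
  tau <- 0.05 * rate
  kt <- seq_len(round(6 * tau))
  kern <- (kt / tau) * exp(-kt / tau)
  train <- numeric(nSamp)
  train[idx] <- stats::runif(length(idx), 0.5, 1.5)
  speechEnv <- causalFilter(train, kern)
  bg <- .convCentered(stats::rnorm(nSamp), stats::dnorm(seq(-15, 15), 0, 3))^2
  bgFast <- .convCentered(stats::rnorm(nSamp), stats::dnorm(seq(-4, 4), 0, 1.2))^2
  env <- 0.45 * pmax(speechEnv, 0) / max(stats::sd(speechEnv), 1e-12) +
    1.0 * bg / max(stats::sd(bg), 1e-12) +
    0.35 * bgFast / max(stats::sd(bgFast), 1e-12) + 0.05
  # pitch: band-limited walk gated by voiced spans of random duration
  voiced <- vapply(fmap, function(f) "voiced" %in% f, TRUE)
  vTrain <- numeric(nSamp)
  vIdx <- idx[voiced[lab]]
  for (i in vIdx)
    vTrain[i:min(nSamp, i + round(stats::runif(1, 0.06, 0.22) * rate))] <- 1
  walk <- cumsum(stats::rnorm(nSamp, 0, 0.8))
  walk <- .convCentered(walk, stats::dnorm(seq(-24, 24), 0, 6))
  walk <- 150 + 60 * (walk - mean(walk)) / max(stats::sd(walk), 1e-9)
  walk <- pmin(300, pmax(50, walk))
  pitch <- walk * vTrain
  # visual PCs: smooth Gaussian processes (autocorrelation width ~200 ms)
  # with a weak faster component so delayed copies stay linearly
  # identifiable, variance ~ 1/j
  gkSlow <- stats::dnorm(seq(-24, 24), 0, 0.035 * rate)
  gkFast <- stats::dnorm(seq(-6, 6), 0, 0.008 * rate)
  vis <- vapply(1:10, function(j) {
    v <- .convCentered(stats::rnorm(nSamp), gkSlow) +
      0.15 * .convCentered(stats::rnorm(nSamp), gkFast)
    v / max(stats::sd(v), 1e-12) / sqrt(j)
  }, numeric(nSamp))
  # scene cuts: Poisson impulses
  cuts <- numeric(nSamp)
  if (cutRate > 0) {
    tc <- cumsum(stats::rexp(max(10, ceiling(3 * cutRate * duration)),
                             cutRate))
    tc <- tc[tc < duration]
    cuts[round(tc * rate) + 1L] <- 1
  }
  m <- cbind(phono, envelope = env, pitch = pitch, vis, scene_cut = cuts)
  FeatureStream(m, .SIM_FEATURES, .SIM_MODALITY, rate)
}

#' Construct the simulator's ground truth
#'
#' True kernels are damped Gabor-shaped temporal responses with random
#' latency 50-350 ms, one per (feature, channel), scaled by topographic
#' modality gains: auditory gains peak over fronto-temporal channels, visual
#' gains over occipital/parietal channels.
#'
#' @param snrDb per-channel SNR of the audiovisual response (dB).
#' @param seed RNG seed.
#' @param channelLabels montage labels.
#' @param lags delay grid the kernels live on.
#' @param rate sampling rate (128).
#' @param phonemeRate,cutRate event rates recorded for provenance.
#' @return a \linkS4class{GroundTruth}.
#' @export
makeGroundTruth <- function(snrDb = 0, seed = 0,
                            channelLabels = defaultMontage64(),
                            lags = defaultLags(), rate = 128,
                            phonemeRate = 6, cutRate = 0.4) {
  set.seed(seed)
  roi <- assignROI(channelLabels)
  aBase <- c(frontal = 1, temporal = 1, central = 0.6, parietal = 0.3,
             occipital = 0.15)
  vBase <- c(occipital = 1, parietal = 0.8, central = 0.35, temporal = 0.2,
             frontal = 0.15)
  nCh <- length(channelLabels)
  aGain <- unname(aBase[roi]) * stats::runif(nCh, 0.9, 1.1)
  vGain <- unname(vBase[roi]) * stats::runif(nCh, 0.9, 1.1)
  nF <- length(.SIM_FEATURES); nL <- length(lags)
  tt <- lags / rate
  kernels <- array(0, c(nF, nL, nCh),
                   dimnames = list(.SIM_FEATURES, NULL, channelLabels))
  for (f in seq_len(nF)) {
    gain <- if (.SIM_MODALITY[f] == "auditory") aGain else vGain
    for (n in seq_len(nCh)) {
      lat <- stats::runif(1, 0.05, 0.35)
      sg <- stats::runif(1, 0.04, 0.09)
      fr <- stats::runif(1, 1.5, 5)
      amp <- stats::rnorm(1, 1, 0.3) / .SIM_FEATURE_SCALE[f]
      kernels[f, , n] <- gain[n] * amp *
        exp(-(tt - lat)^2 / (2 * sg^2)) * cos(2 * pi * fr * (tt - lat))
    }
  }
  new("GroundTruth", kernels = kernels,
      auditoryGain = stats::setNames(aGain, channelLabels),
      visualGain = stats::setNames(vGain, channelLabels),
      snrDb = snrDb, seed = as.integer(seed), phonemeRate = phonemeRate,
      cutRate = cutRate, lags = as.integer(lags),
      featureNames = .SIM_FEATURES, channelLabels = channelLabels,
      modality = .SIM_MODALITY)
}

#' Channels strongly driven by a modality
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param modality "auditory" or "visual".
#' @param threshold fraction of the maximum gain.
#' @return character vector of channel labels.
#' @export
drivenChannels <- function(truth, modality = c("auditory", "visual"),
                           threshold = 0.7) {
  modality <- match.arg(modality)
  g <- if (modality == "auditory") truth@auditoryGain else truth@visualGain
  names(g)[g >= threshold * max(g)]
}

# Convolve a feature block with its kernels: returns time x channels.
.kernelResponse <- function(sm, kernels, lags) {
  if (!ncol(sm)) return(matrix(0, nrow(sm), dim(kernels)[3]))
  S <- delayEmbed(sm, lags)
  W <- matrix(aperm(kernels, c(2, 1, 3)), nrow = dim(kernels)[1] * dim(kernels)[2])
  S %*% W
}

#' Simulate an EEG epoch from features and ground truth
#'
#' \code{y(t, n) = sum_f sum_tau w_true(f, tau, n) s(f, t - tau) + noise};
#' the A condition zeroes the visual contribution, V zeroes the auditory
#' one, AV keeps both. Noise is 1/f-shaped Gaussian band-limited to 1-15 Hz,
#' scaled per channel so that the full audiovisual response attains
#' \code{snrDb} (gain zeroing happens after scaling, so unimodal conditions
#' carry the same noise level).
#'
#' @param features a \linkS4class{FeatureStream} from
#'   \code{\link{simulateFeatures}}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param condition "AV", "A" or "V".
#' @param noise logical; disable for exact kernel-sum outputs.
#' @param seed RNG seed for the noise draw.
#' @param subjectId,trailerId tags for the epoch.
#' @param conditionGains optional named list, e.g.
#'   \code{list(auditory = 1, visual = 1)}, modulating the retained
#'   modalities (multimodal interaction; default off).
#' @return an \linkS4class{EEGEpoch}.
#' @export
simulateEEG <- function(features, truth, condition = c("AV", "A", "V"),
                        noise = TRUE, seed = 0, subjectId = "S01",
                        trailerId = "tr01",
                        conditionGains = list(auditory = 1, visual = 1)) {
  condition <- match.arg(condition)
  sig <- .modalitySignals(features, truth)
  .epochFromSignals(sig, truth, condition, noise, seed, subjectId,
                    trailerId, conditionGains, rate = sampleRate(features))
}

# Per-modality kernel-convolved responses, computed once per feature stream.
.modalitySignals <- function(features, truth) {
  if (!identical(featureNames(features), truth@featureNames))
    stop("features do not match the ground-truth kernel axis")
  sm <- streamData(features)
  aud <- truth@modality == "auditory"
  list(sa = .kernelResponse(sm[, aud, drop = FALSE],
                            truth@kernels[aud, , , drop = FALSE],
                            truth@lags),
       sv = .kernelResponse(sm[, !aud, drop = FALSE],
                            truth@kernels[!aud, , , drop = FALSE],
                            truth@lags))
}

.epochFromSignals <- function(sig, truth, condition, noise, seed, subjectId,
                              trailerId,
                              conditionGains = list(auditory = 1, visual = 1),
                              rate = 128) {
  gA <- conditionGains$auditory %||% 1
  gV <- conditionGains$visual %||% 1
  signal <- switch(condition,
                   AV = gA * sig$sa + gV * sig$sv,
                   A = gA * sig$sa,
                   V = gV * sig$sv)
  if (noise) {
    set.seed(seed)
    nT <- nrow(signal)
    sdSig <- sqrt(apply(sig$sa, 2L, stats::var) +
                    2 * vapply(seq_len(ncol(signal)), function(n)
                      stats::cov(sig$sa[, n], sig$sv[, n]), 0) +
                    apply(sig$sv, 2L, stats::var))
    sdNoise <- sdSig / 10^(truth@snrDb / 20)
    for (n in seq_along(sdNoise))
      signal[, n] <- signal[, n] + pinkNoise(nT, rate) * sdNoise[n]
  }
  EEGEpoch(t(signal), truth@channelLabels, condition, subjectId, trailerId)
}

#' Generate a full multi-trailer, three-condition dataset
#'
#' Per trailer: one feature stream (shared verbatim across conditions) and
#' one EEG epoch per condition, with independent noise draws. The last two
#' trailers are designated as the held-out test set. Fully reproducible from
#' \code{seed}.
#'
#' @param nTrailers number of trailers (>= 3; default 8).
#' @param duration per-trailer duration in seconds (150).
#' @param snrDb simulator SNR (0 dB).
#' @param seed base seed.
#' @param phonemeRate,cutRate event rates.
#' @param subjectId subject tag.
#' @param conditionGains see \code{\link{simulateEEG}}.
#' @return a \linkS4class{SimulatedDataset}.
#' @export
makeDataset <- function(nTrailers = 8, duration = 150, snrDb = 0, seed = 0,
                        phonemeRate = 6, cutRate = 0.4, subjectId = "S01",
                        conditionGains = list(auditory = 1, visual = 1)) {
  if (nTrailers < 3) stop("need at least 3 trailers")
  truth <- makeGroundTruth(snrDb, childSeed(seed, 0),
                           phonemeRate = phonemeRate, cutRate = cutRate)
  ids <- sprintf("tr%02d", seq_len(nTrailers))
  features <- list(); eeg <- list()
  for (k in seq_len(nTrailers)) {
    fs <- simulateFeatures(duration, childSeed(seed, k), phonemeRate,
                           cutRate)
    features[[ids[k]]] <- fs
    sig <- .modalitySignals(fs, truth)   # shared across conditions
    eeg[[ids[k]]] <- stats::setNames(lapply(seq_along(.CONDITIONS),
      function(c) .epochFromSignals(sig, truth, .CONDITIONS[c], TRUE,
                                    childSeed(seed, 100 + 3 * k + c),
                                    subjectId, ids[k], conditionGains)),
      .CONDITIONS)
    gc(FALSE)  # each trailer's embedding temporaries are large
  }
  new("SimulatedDataset", features = features, eeg = eeg, truth = truth,
      testTrailers = ids[(nTrailers - 1):nTrailers])
}

#' Subset a simulated feature stream to one modality family
#'
#' @param features a \linkS4class{FeatureStream}.
#' @param family "auditory" or "visual".
#' @return the family's \linkS4class{FeatureStream}.
#' @export
featureFamily <- function(features, family = c("auditory", "visual")) {
  family <- match.arg(family)
  keep <- modality(features) == family
  FeatureStream(streamData(features)[, keep, drop = FALSE],
                featureNames(features)[keep], family, sampleRate(features))
}

#' Generate deterministic toy video frames
#'
#' Raw 720 x 1280 RGB frame stacks for testing the visual pipeline: blank,
#' a full-field drifting grating (in the coordinates of the final padded
#' square, so spatial frequency is in cycles/image after preprocessing), or
#' seeded white noise.
#'
#' @param kind "blank", "drifting_grating" or "noise".
#' @param nFrames number of frames.
#' @param spatialFreq grating spatial frequency (cycles/image).
#' @param direction drift direction, degrees.
#' @param temporalFreq drift rate, Hz.
#' @param frameRate frames/s (24).
#' @param contrast grating contrast in [0, 1].
#' @param seed RNG seed for noise.
#' @return a 720 x 1280 x 3 x nFrames array in [0, 1].
#' @export
makeToyVideo <- function(kind = c("blank", "drifting_grating", "noise"),
                         nFrames = 10, spatialFreq = 6, direction = 0,
                         temporalFreq = 4 / 3, frameRate = 24, contrast = 1,
                         seed = 0) {
  kind <- match.arg(kind)
  if (nFrames < 1) stop("nFrames must be >= 1")
  out <- array(0, c(720, 1280, 3, nFrames))
  if (kind == "blank") return(out)
  if (kind == "noise") {
    set.seed(seed)
    out[] <- stats::runif(length(out))
    return(out)
  }
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  # coordinates of the padded 1280 x 1280 square, as image fractions
  x <- (seq_len(1280) - 0.5) / 1280
  y <- (seq_len(720) + 280 - 0.5) / 1280
  th <- direction * pi / 180
  phase <- 2 * pi * spatialFreq * outer(y * sin(th), x * cos(th), "+")
  for (t in seq_len(nFrames)) {
    g <- 0.5 + 0.5 * contrast *
      cos(phase - 2 * pi * temporalFreq * (t - 1) / frameRate)
    out[, , 1, t] <- g; out[, , 2, t] <- g; out[, , 3, t] <- g
  }
  out
}
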