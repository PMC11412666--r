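# Shared fixtures and small generators used across the suite. Everything is
# built in code at test time; nothing is read from disk except files the
# tests themselves write to tempdir().

sineAudio <- function(freq, duration, rate = 44100, amplitude = 1,
                      phase = 0) {
  t <- seq_len(round(duration * rate)) / rate
  AudioSignal(amplitude * sin(2 * pi * freq * t + phase), rate)
}

# A three-tier annotation: phonemes, words, scene-cut points.
threeTierAnnotation <- function() {
  AnnotationTrack(list(
    phoneme = data.frame(start = c(0.10, 0.25, 0.40),
                         end = c(0.18, 0.33, 0.52),
                         label = c("S", "AA", "T")),
    word = data.frame(start = 0.10, end = 0.52, label = "sat"),
    scene = data.frame(start = c(1.0, 2.5), end = c(1.0, 2.5),
                       label = c("cut", "cut"))))
}

# Write a 2-channel 16-bit PCM WAV with given channel vectors.
writeStereoWav <- function(path, left, right, rate = 8000) {
  pcm <- as.integer(round(rbind(left, right) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 2L), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 4), con, 4, endian = "little")
  writeBin(c(4L, 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(as.vector(pcm), con, 2, endian = "little")
  invisible(path)
}

# Write a minimal continuous EDF file from a channels x samples matrix of
# integers (stored with unit scaling).
writeTinyEDF <- function(path, data, rate) {
  ns <- nrow(data); spr <- as.integer(rate); nRec <- ncol(data) %/% spr
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  hdr <- paste0(pad("0", 8), pad("patient", 80), pad("recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(nRec, 8),
                pad(1, 8), pad(ns, 4))
  sig <- paste0(paste(pad(paste0("EEG", seq_len(ns)), 16), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad("uV", 8), ns), collapse = ""),
                paste(rep(pad(-32768, 8), ns), collapse = ""),
                paste(rep(pad(32767, 8), ns), collapse = ""),
                paste(rep(pad(-32768, 8), ns), collapse = ""),
                paste(rep(pad(32767, 8), ns), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad(spr, 8), ns), collapse = ""),
                paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(data[, idx, drop = FALSE])), con, 2,
             endian = "little")
  }
  invisible(path)
}

# Drifting-grating luminance movie directly at bank resolution (96 x 96).
gratingMovie <- function(nFrames, spatialFreq, direction, temporalFreq,
                         frameRate = 24, size = 96, contrast = 1,
                         spatialPhase = 0) {
  px <- (seq_len(size) - 0.5) / size
  th <- direction * pi / 180
  sp <- 2 * pi * spatialFreq * outer(px * sin(th), px * cos(th), "+")
  out <- array(0, c(size, size, nFrames))
  for (t in seq_len(nFrames))
    out[, , t] <- 0.5 + 0.5 * contrast *
      cos(sp + spatialPhase - 2 * pi * temporalFreq * (t - 1) / frameRate)
  out
}

# Cache for the expensive acceptance-scale pipeline, shared across test
# blocks within one session.
.acceptanceCache <- new.env(parent = emptyenv())

acceptancePipeline <- function() {
  if (!is.null(.acceptanceCache$fits)) return(.acceptanceCache$fits)
  ds <- makeDataset(nTrailers = 8, duration = 150, snrDb = 0, seed = 0)
  split <- splitByTrailer(ds, ds@testTrailers)
  out <- list(ds = ds, split = split)
  for (fam in c("auditory", "visual")) {
    uniCond <- if (fam == "auditory") "A" else "V"
    trainStim <- concatenateStreams(
      lapply(ds@features[split$train], featureFamily, fam))
    testStim <- concatenateStreams(
      lapply(ds@features[split$test], featureFamily, fam))
    yTrainUni <- concatenateEpochs(
      lapply(ds@eeg[split$train], `[[`, uniCond))
    yTrainAV <- concatenateEpochs(lapply(ds@eeg[split$train], `[[`, "AV"))
    yTestUni <- concatenateEpochs(lapply(ds@eeg[split$test], `[[`, uniCond))
    res <- runConditionAnalysis(
      trainStim, list(uni = yTrainUni, AV = yTrainAV), testStim, yTestUni,
      seed = 7, nShuffles = 100, shuffleFor = "uni",
      trainTrailers = split$train)
    rm(yTrainUni, yTrainAV); gc(FALSE)
    evCross <- crossPredict(res$models$AV, testStim, yTestUni,
                            modelTag = paste0(fam, "_cross"))
    out[[fam]] <- list(modelUni = res$models$uni, modelAV = res$models$AV,
                       within = res$evals$uni, cross = evCross,
                       shuffle = res$evals$uni)
    rm(res); gc(FALSE)
  }
  .acceptanceCache$fits <- out
  out
}
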