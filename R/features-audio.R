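# Auditory features: 14 binary phonological-onset streams, acoustic envelope,
# autocorrelation pitch. All outputs are FeatureStreams at 128 Hz.

.PHONO_FEATURES <- c("sonorant", "obstruent", "voiced", "nasal", "syllabic",
                     "fricative", "plosive", "labial", "coronal", "dorsal",
                     "front", "back", "high", "low")

#' Default ARPAbet phoneme-to-phonological-feature map
#'
#' Place/manner/voicing articulatory classes for the ARPAbet inventory; 14
#' distinct features in total (sonorant, obstruent, voiced, nasal, syllabic,
#' fricative, plosive, labial, coronal, dorsal, front, back, high, low).
#' Override with any named list of character vectors drawn from the same
#' feature set.
#'
#' @return named list: phoneme -> character vector of features.
#' @export
defaultPhonemeFeatureMap <- function() {
  V <- function(...) unique(c("sonorant", "voiced", "syllabic", ...))
  list(
    # vowels
    AA = V("low", "back"),   AE = V("low", "front"), AH = V("back"),
    AO = V("low", "back"),   AW = V("low", "back"),  AY = V("low", "front"),
    EH = V("front"),         ER = V("back"),         EY = V("front"),
    IH = V("high", "front"), IY = V("high", "front"),
    OW = V("back"),          OY = V("back"),
    UH = V("high", "back"),  UW = V("high", "back"),
    # nasals / approximants
    M = c("sonorant", "voiced", "nasal", "labial"),
    N = c("sonorant", "voiced", "nasal", "coronal"),
    NG = c("sonorant", "voiced", "nasal", "dorsal"),
    L = c("sonorant", "voiced", "coronal"),
    R = c("sonorant", "voiced", "coronal"),
    W = c("sonorant", "voiced", "labial", "high"),
    Y = c("sonorant", "voiced", "dorsal", "high", "front"),
    # obstruents
    P = c("obstruent", "plosive", "labial"),
    B = c("obstruent", "plosive", "voiced", "labial"),
    T = c("obstruent", "plosive", "coronal"),
    D = c("obstruent", "plosive", "voiced", "coronal"),
    K = c("obstruent", "plosive", "dorsal"),
    G = c("obstruent", "plosive", "voiced", "dorsal"),
    CH = c("obstruent", "plosive", "fricative", "coronal"),
    JH = c("obstruent", "plosive", "fricative", "voiced", "coronal"),
    F = c("obstruent", "fricative", "labial"),
    V = c("obstruent", "fricative", "voiced", "labial"),
    TH = c("obstruent", "fricative", "coronal"),
    DH = c("obstruent", "fricative", "voiced", "coronal"),
    S = c("obstruent", "fricative", "coronal"),
    Z = c("obstruent", "fricative", "voiced", "coronal"),
    SH = c("obstruent", "fricative", "coronal", "high"),
    ZH = c("obstruent", "fricative", "voiced", "coronal", "high"),
    HH = c("obstruent", "fricative"))
}

#' Binary phonological-onset matrix
#'
#' For each phoneme interval in the annotation's phoneme tier, places a single
#' 1 at the sample nearest the phoneme onset in every feature column the
#' phoneme carries (onset coding). \code{durationCoding = TRUE} instead sets
#' 1 over the whole interval.
#'
#' @param annot an \linkS4class{AnnotationTrack} with a phoneme tier.
#' @param fmap named list phoneme -> feature subset; unknown labels are
#'   skipped with a message.
#' @param duration stream duration in seconds.
#' @param tier name of the phoneme tier.
#' @param rate output rate (128 Hz).
#' @param durationCoding logical; see above.
#' @return a (time x 14) binary \linkS4class{FeatureStream}.
#' @export
phonologicalMatrix <- function(annot, fmap = defaultPhonemeFeatureMap(),
                               duration, tier = "phoneme", rate = 128,
                               durationCoding = FALSE) {
  tl <- tiers(annot)
  if (!tier %in% names(tl)) stop("annotation has no '", tier, "' tier")
  ph <- tl[[tier]]
  ph <- ph[nzchar(trimws(ph$label)), , drop = FALSE]
  nSamp <- round(duration * rate)
  if (nrow(ph) && max(ph$start) > duration)
    stop("duration is shorter than the last phoneme onset")
  m <- matrix(0, nSamp, length(.PHONO_FEATURES),
              dimnames = list(NULL, .PHONO_FEATURES))
  unknown <- character(0)
  for (k in seq_len(nrow(ph))) {
    lab <- toupper(gsub("[0-9]", "", trimws(ph$label[k])))
    feats <- fmap[[lab]]
    if (is.null(feats)) { unknown <- c(unknown, lab); next }
    i0 <- min(nSamp, round(ph$start[k] * rate) + 1L)
    idx <- if (durationCoding)
      i0:min(nSamp, max(i0, round(ph$end[k] * rate))) else i0
    m[idx, feats] <- 1
  }
  if (length(unknown))
    message("skipped phoneme label(s) with no feature-map entry: ",
            paste(unique(unknown), collapse = ", "))
  FeatureStream(m, .PHONO_FEATURES, "auditory", rate)
}

#' Acoustic envelope at 128 Hz
#'
#' Magnitude of the analytic (Hilbert) signal, low-passed with a third-order
#' Butterworth at 25 Hz (zero-phase), resampled to 128 Hz, with residual
#' negative ripple clipped to zero.
#'
#' @param audio an \linkS4class{AudioSignal} (rate > 2 kHz).
#' @return a one-column \linkS4class{FeatureStream}.
#' @export
acousticEnvelope <- function(audio) {
  x <- samples(audio)
  if (!length(x)) stop("empty audio")
  fs <- sampleRate(audio)
  if (fs <= 2000) stop("acousticEnvelope expects audio sampled above 2 kHz")
  env <- Mod(analyticSignal(x))
  bw <- signal::butter(3, 25 / (fs / 2))
  env <- signal::filtfilt(bw, env)
  env <- fftResample(env, fs, 128)
  env[env < 0] <- 0
  FeatureStream(matrix(env, ncol = 1), "envelope", "auditory", 128)
}

#' Autocorrelation pitch track at 128 Hz
#'
#' Frame-wise normalized autocorrelation F0 estimation on a 1/128 s hop grid,
#' restricted to the 50-300 Hz range; frames whose peak normalized
#' autocorrelation falls below \code{periodicityFloor} are reported as 0
#' (unvoiced). The analysis window (default 40 ms) covers two periods of the
#' lowest admissible F0. A parabolic refinement of the peak lag gives
#' sub-sample resolution.
#'
#' @param audio an \linkS4class{AudioSignal} (rate >= 8 kHz).
#' @param f0Range admissible F0 range in Hz.
#' @param windowSec analysis window length in seconds.
#' @param periodicityFloor voiced/unvoiced threshold on the normalized
#'   autocorrelation peak.
#' @return a one-column \linkS4class{FeatureStream} (Hz; 0 = unvoiced).
#' @export
pitchTrack <- function(audio, f0Range = c(50, 300), windowSec = 0.040,
                       periodicityFloor = 0.3) {
  x <- samples(audio)
  if (!length(x)) stop("empty audio")
  fs <- sampleRate(audio)
  if (fs < 8000) stop("pitchTrack expects audio sampled at >= 8 kHz")
  hop <- fs / 128
  win <- round(windowSec * fs)
  lagMin <- max(2L, floor(fs / f0Range[2]))
  lagMax <- ceiling(fs / f0Range[1])
  if (win <= lagMax) win <- lagMax + 1L
  nFrames <- floor(length(x) / hop)
  f0 <- numeric(nFrames)
  for (k in seq_len(nFrames)) {
    i0 <- round((k - 1) * hop) + 1L
    if (i0 + win - 1L > length(x)) break  # require a full analysis window
    seg <- x[i0:(i0 + win - 1L)]
    seg <- seg - mean(seg)
    e0 <- sum(seg^2)
    if (e0 < 1e-12) next
    n <- length(seg)
    # autocorrelation via the FFT power spectrum (zero-padded)
    m <- stats::nextn(2L * n, 2)
    P <- stats::fft(c(seg, numeric(m - n)))
    ac <- Re(stats::fft(P * Conj(P), inverse = TRUE))[1:(lagMax + 1L)] / m
    acn <- ac / ac[1]
    band <- (lagMin + 1L):(lagMax + 1L)
    pk <- band[which.max(acn[band])]
    if (acn[pk] < periodicityFloor) next
    # parabolic interpolation around the peak lag
    lag <- pk - 1L
    if (pk > 2L && pk < lagMax + 1L) {
      y1 <- acn[pk - 1L]; y2 <- acn[pk]; y3 <- acn[pk + 1L]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / den
    }
    f0[k] <- fs / lag
  }
  FeatureStream(matrix(f0, ncol = 1), "pitch", "auditory", 128)
}
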