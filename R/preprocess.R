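# Preprocessing chain: mastoid re-reference, notch + band-pass filtering,
# resampling to 128 Hz, stimulus alignment, epoching.

#' Re-reference to the average of the mastoids (TP9/TP10)
#'
#' Subtracts 0.5*(TP9 + TP10) from every channel, sample-wise.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @return the re-referenced recording.
#' @export
rereferenceMastoids <- function(rec) {
  labels <- channelLabels(rec)
  for (m in c("TP9", "TP10"))
    if (!m %in% labels) stop("mastoid channel missing: ", m)
  ref <- 0.5 * (rec@data[match("TP9", labels), ] +
                  rec@data[match("TP10", labels), ])
  EEGRecording(sweep(rec@data, 2L, ref, "-"), sampleRate(rec), labels,
               rec@auxAudio, rec@auxRate)
}

#' Notch (58-62 Hz) then 1-15 Hz zero-phase FIR band-pass
#'
#' Both filters are Hamming-window linear-phase FIR kernels applied in a
#' single pass with group-delay compensation (zero net phase). The channel
#' mean is removed first; both steps are linear. The notch is skipped when
#' the sampling rate cannot represent 60 Hz.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param bandpass lower/upper passband edges in Hz.
#' @param notch logical; apply the 58-62 Hz band-stop.
#' @param transitionHz transition width controlling the Hamming-rule kernel
#'   length.
#' @return the filtered recording.
#' @export
filterChain <- function(rec, bandpass = c(1, 15), notch = TRUE,
                        transitionHz = 1) {
  fs <- sampleRate(rec)
  if (fs < 128) stop("filterChain expects a sampling rate >= 128 Hz")
  nyq <- fs / 2
  nBand <- firLength(fs, transitionHz)
  if (ncol(rec@data) < 3L * nBand)
    stop("signal too short for the filter kernel (need >= ",
         3L * nBand, " samples)")
  bBand <- signal::fir1(nBand - 1L, bandpass / nyq, type = "pass",
                        window = signal::hamming(nBand))
  doNotch <- notch && nyq > 62
  if (doNotch) {
    nNotch <- firLength(fs, transitionHz)
    bNotch <- signal::fir1(nNotch - 1L, c(58, 62) / nyq, type = "stop",
                           window = signal::hamming(nNotch))
  }
  out <- rec@data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    if (doNotch) x <- firZeroPhase(x, bNotch)
    out[i, ] <- firZeroPhase(x, bBand)
  }
  EEGRecording(out, fs, channelLabels(rec), rec@auxAudio, rec@auxRate)
}

#' Resample a recording to 128 Hz
#'
#' Fourier-domain (band-limited) resampling: zero-phase, with anti-aliasing
#' implicit in the spectrum truncation.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @return the recording at 128 Hz (length scaled by 128/rate).
#' @export
resampleTo128 <- function(rec) {
  fs <- sampleRate(rec)
  if (fs == 128) return(rec)
  if (fs < 128) stop("resampleTo128 expects a sampling rate >= 128 Hz")
  out <- t(apply(rec@data, 1L, fftResample, rateIn = fs, rateOut = 128))
  EEGRecording(out, 128, channelLabels(rec), rec@auxAudio, rec@auxRate)
}

#' Locate the stimulus onset in the recorded audio channel
#'
#' Matched-filter alignment: the stimulus waveform is slid along the recorded
#' auxiliary audio and the lag maximizing the normalized cross-correlation is
#' returned. By default both signals are reduced to amplitude envelopes
#' (rectified, 25 Hz low-passed) for robustness; \code{mode = "waveform"}
#' correlates the raw waveforms.
#'
#' @param auxAudio numeric vector: the audio channel recorded with the EEG.
#' @param stimAudio an \linkS4class{AudioSignal}, resampled internally to the
#'   recording rate if needed.
#' @param rate sampling rate of \code{auxAudio}.
#' @param mode "envelope" or "waveform".
#' @param minCorrelation correlation floor below which alignment fails.
#' @return list with \code{lag} (samples, 0-based) and \code{correlation}.
#' @export
alignStimulus <- function(auxAudio, stimAudio, rate,
                          mode = c("envelope", "waveform"),
                          minCorrelation = 0.2) {
  mode <- match.arg(mode)
  stim <- samples(stimAudio)
  if (sampleRate(stimAudio) != rate)
    stim <- fftResample(stim, sampleRate(stimAudio), rate)
  if (length(stim) > length(auxAudio))
    stop("stimulus is longer than the recorded audio")
  a <- auxAudio; s <- stim
  if (mode == "envelope") {
    bw <- signal::butter(3, min(0.9, 25 / (rate / 2)))
    a <- signal::filtfilt(bw, abs(a))
    s <- signal::filtfilt(bw, abs(s))
  }
  s <- s - mean(s)
  n <- length(a); m <- length(s)
  nfft <- stats::nextn(n + m, 2)
  # cross-correlation of the template against every window start, via FFT
  num <- Re(stats::fft(stats::fft(c(a, numeric(nfft - n))) *
                         Conj(stats::fft(c(s, numeric(nfft - m)))),
                       inverse = TRUE)) / nfft
  num <- num[seq_len(n - m + 1L)]
  # sliding mean / energy of the aux windows, via cumulative sums
  c1 <- cumsum(c(0, a)); c2 <- cumsum(c(0, a^2))
  winSum <- c1[(m + 1):(n + 1)] - c1[1:(n - m + 1)]
  winSq <- c2[(m + 1):(n + 1)] - c2[1:(n - m + 1)]
  denom <- sqrt(pmax(winSq - winSum^2 / m, 0) * sum(s^2))
  score <- ifelse(denom > 0, num / denom, 0)
  best <- which.max(score)
  if (!is.finite(score[best]) || score[best] < minCorrelation)
    stop("alignment not found (peak correlation ",
         sprintf("%.3f", max(score, na.rm = TRUE)), " below floor)")
  list(lag = best - 1L, correlation = score[best])
}

#' Slice a 128 Hz recording into a condition-tagged epoch
#'
#' @param rec an \linkS4class{EEGRecording} at 128 Hz (resample first).
#' @param onset stimulus onset, in samples at the recording rate (0-based).
#' @param duration epoch duration in seconds.
#' @param condition one of "AV", "A", "V".
#' @param subjectId,trailerId provenance tags.
#' @return an \linkS4class{EEGEpoch}.
#' @export
epochRecording <- function(rec, onset, duration, condition,
                           subjectId = "S01", trailerId = "tr01") {
  if (sampleRate(rec) != 128)
    stop("epochRecording expects a 128 Hz recording; resample first")
  nSamp <- round(duration * 128)
  from <- onset + 1L
  to <- onset + nSamp
  if (from < 1L || to > ncol(rec@data))
    stop("epoch [", from, ", ", to, "] is out of bounds (recording has ",
         ncol(rec@data), " samples)")
  EEGEpoch(rec@data[, from:to, drop = FALSE], channelLabels(rec), condition,
           subjectId, trailerId)
}
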