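# Minimal RIFF/WAVE reading and writing (PCM 16/24/32-bit and IEEE float32).

#' Read a WAV file as a mono AudioSignal
#'
#' Multi-channel audio is averaged to mono; samples are scaled to [-1, 1].
#'
#' @param path file path.
#' @return an \linkS4class{AudioSignal}.
#' @export
readAudio <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id) || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        nChannels = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)
  x <- switch(as.character(fmt$audioFormat),
    "1" = switch(as.character(fmt$bits),
      "16" = readBin(dat, "integer", length(dat) / 2, 2, endian = "little") / 32768,
      "32" = readBin(dat, "integer", length(dat) / 4, 4, endian = "little") / 2147483648,
      "8"  = (readBin(dat, "integer", length(dat), 1, signed = FALSE) - 128) / 128,
      stop("unsupported PCM bit depth: ", fmt$bits)),
    "3" = readBin(dat, "double", length(dat) / 4, 4, endian = "little"),
    stop("unsupported WAV codec (format tag ", fmt$audioFormat, ")"))
  if (fmt$nChannels > 1L) {
    x <- matrix(x, nrow = fmt$nChannels)
    x <- colMeans(x)
  }
  AudioSignal(x, fmt$rate)
}

#' Write an AudioSignal as a 16-bit PCM WAV file
#'
#' @param audio an \linkS4class{AudioSignal} (values clipped to [-1, 1]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAudio <- function(audio, path) {
  x <- pmin(1, pmax(-1, samples(audio)))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")            # PCM, mono
  writeBin(as.integer(sampleRate(audio)), con, 4, endian = "little")
  writeBin(as.integer(sampleRate(audio) * 2), con, 4, endian = "little")
  writeBin(c(2L, 16L), con, 2, endian = "little")           # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
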