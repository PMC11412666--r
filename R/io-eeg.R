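# EEG and feature-stream I/O: BrainVision and EDF readers, plus the package's
# own single-file matrix container (JSON header + raw little-endian doubles),
# chosen for bit-exact round trips.

.MAGIC <- "AVT1"

.writeContainer <- function(path, header, mat) {
  hdr <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.MAGIC, con, eos = NULL)
  writeBin(length(hraw), con, 4, endian = "little")
  writeBin(hraw, con)
  writeBin(as.vector(mat), con, 8, endian = "little")
  invisible(path)
}

.readContainer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), .MAGIC))
    stop("not an avTRF container: ", path)
  n <- readBin(con, "integer", 1, 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  k <- prod(unlist(header$dim))
  mat <- matrix(readBin(con, "double", k, 8, endian = "little"),
                header$dim[1], header$dim[2])
  list(header = header, mat = mat)
}

#' Write an EEGRecording or EEGEpoch to the internal container
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{EEGEpoch}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEEGContainer <- function(x, path) {
  header <- list(type = "eeg", dim = dim(epochData(x)), rate = sampleRate(x),
                 labels = channelLabels(x))
  if (is(x, "EEGEpoch")) {
    header$condition <- condition(x)
    header$subject <- subjectId(x)
    header$trailer <- trailerId(x)
  }
  .writeContainer(path, header, epochData(x))
}

#' Read the internal EEG container
#'
#' Returns an \linkS4class{EEGEpoch} when condition tags are present,
#' otherwise an \linkS4class{EEGRecording}.
#'
#' @param path file path.
#' @export
readEEGContainer <- function(path) {
  r <- .readContainer(path)
  h <- r$header
  if (!identical(h$type, "eeg")) stop("container does not hold EEG: ", path)
  if (length(h$labels) != nrow(r$mat))
    stop("container label count does not match matrix rows in ", path)
  if (!is.null(h$condition))
    EEGEpoch(r$mat, h$labels, h$condition, h$subject, h$trailer)
  else
    EEGRecording(r$mat, h$rate, h$labels)
}

#' Write/read a FeatureStream to/from the internal container
#'
#' @param x a \linkS4class{FeatureStream}.
#' @param path file path.
#' @export
writeFeatureContainer <- function(x, path) {
  .writeContainer(path, list(type = "features", dim = dim(streamData(x)),
                             rate = sampleRate(x), names = featureNames(x),
                             modality = modality(x)), streamData(x))
}

#' @rdname writeFeatureContainer
#' @export
readFeatureContainer <- function(path) {
  r <- .readContainer(path)
  h <- r$header
  if (!identical(h$type, "features")) stop("container does not hold features: ", path)
  FeatureStream(r$mat, h$names, h$modality, h$rate)
}

#' Read EEG from BrainVision, EDF, or the internal container
#'
#' Dispatches on the file extension: \code{.vhdr} (BrainVision header),
#' \code{.edf}, anything else is treated as the internal container.
#'
#' @param path file path.
#' @return an \linkS4class{EEGRecording} (or \linkS4class{EEGEpoch} from a
#'   tagged container).
#' @export
readEEG <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vhdr = readBrainVision(path),
         edf = readEDF(path),
         readEEGContainer(path))
}

#' Read a BrainVision recording (.vhdr + .eeg, binary multiplexed)
#'
#' @param path path to the .vhdr header file.
#' @return an \linkS4class{EEGRecording}.
#' @export
readBrainVision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getKey <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "="), "", hit[1])
  }
  dataFile <- file.path(dirname(path), getKey("DataFile"))
  markerFile <- getKey("MarkerFile")
  if (!file.exists(dataFile))
    stop("BrainVision data file missing: ", basename(dataFile))
  if (!is.na(markerFile) &&
      !file.exists(file.path(dirname(path), markerFile)))
    stop("BrainVision marker file missing: ", markerFile)
  nCh <- as.integer(getKey("NumberOfChannels"))
  rate <- 1e6 / as.numeric(getKey("SamplingInterval"))
  fmt <- getKey("BinaryFormat")
  orient <- getKey("DataOrientation")
  chLines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  chInfo <- strsplit(sub("^Ch[0-9]+=", "", chLines), ",")
  labels <- vapply(chInfo, `[`, "", 1L)
  res <- vapply(chInfo, function(v)
    if (length(v) >= 3 && nzchar(v[3])) as.numeric(v[3]) else 1, 0)
  sz <- file.info(dataFile)$size
  con <- file(dataFile, "rb")
  on.exit(close(con))
  if (identical(fmt, "INT_16")) {
    raw <- readBin(con, "integer", sz / 2, 2, endian = "little")
  } else { # IEEE_FLOAT_32
    raw <- readBin(con, "double", sz / 4, 4, endian = "little")
  }
  if (identical(orient, "VECTORIZED")) {
    m <- t(matrix(raw, ncol = nCh))
  } else {
    m <- matrix(raw, nrow = nCh)
  }
  m <- m * res
  EEGRecording(m, rate, labels)
}

#' Read an EDF recording (continuous, 16-bit)
#'
#' All signals must share a sampling rate; physical scaling is applied.
#'
#' @param path path to the .edf file.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  invisible(rd(8 + 80 + 80 + 8 + 8))     # version, patient, recording, date, time
  invisible(rd(8))                       # header length
  invisible(rd(44))
  nRec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  invisible(rd(80 * ns))                 # transducer
  invisible(rd(8 * ns))                  # physical dim
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  invisible(rd(80 * ns))                 # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  invisible(rd(32 * ns))
  if (length(unique(spr)) != 1L)
    stop("EDF signals with heterogeneous sampling rates are not supported")
  rate <- spr[1] / dur
  data <- matrix(0, ns, nRec * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  scale[!is.finite(scale)] <- 1
  for (r in seq_len(nRec)) {
    block <- readBin(con, "integer", ns * spr[1], 2, endian = "little")
    block <- matrix(block, nrow = spr[1])  # one column per signal
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(sweep(sweep(block, 2L, digMin, "-"), 2L, scale, "*") +
                       rep(physMin, each = spr[1]))
  }
  EEGRecording(data, rate, make.unique(labels))
}
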