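# Visual features: frame preprocessing, the spatiotemporal Gabor
# motion-energy bank, PCA reduction, scene-cut impulses.

#' Preprocess raw RGB video frames
#'
#' Pads 720 x 1280 RGB frames to 1280 x 1280 with black rows (top/bottom),
#' downsamples to \code{size} x \code{size}, converts to L*a*b* and retains
#' the luminance channel L* scaled to [0, 1].
#'
#' @param raw a 720 x 1280 x 3 x T array (or 720 x 1280 x 3 for one frame),
#'   sRGB values in [0, 1].
#' @param size output side length in pixels (96).
#' @return a \code{size} x \code{size} x T luminance array in [0, 1].
#' @export
preprocessFrames <- function(raw, size = 96) {
  if (length(dim(raw)) == 3L) dim(raw) <- c(dim(raw), 1L)
  d <- dim(raw)
  if (d[1] != 720 || d[2] != 1280 || d[3] != 3)
    stop("frames must be 720 x 1280 x 3 (x T); got ",
         paste(d, collapse = " x "))
  nT <- d[4]
  pad <- (1280 - 720) %/% 2
  out <- array(0, c(size, size, nT))
  for (t in seq_len(nT)) {
    rgbSmall <- array(0, c(size, size, 3))
    for (c in 1:3) {
      full <- matrix(0, 1280, 1280)
      full[(pad + 1):(pad + 720), ] <- raw[, , c, t]
      rgbSmall[, , c] <- EBImage::resize(full, w = size, h = size)
    }
    out[, , t] <- .rgb2L(rgbSmall) / 100
  }
  out
}

# sRGB (0-1) -> CIE L* (0-100), D65.
.rgb2L <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  Y <- 0.2126729 * lin[, , 1] + 0.7151522 * lin[, , 2] + 0.0721750 * lin[, , 3]
  f <- ifelse(Y > (6 / 29)^3, Y^(1 / 3), Y / (3 * (6 / 29)^2) + 4 / 29)
  116 * f - 16
}

#' Build the spatiotemporal Gabor motion-energy bank
#'
#' Quadrature-pair spatiotemporal Gabor filters on a centered lattice: five
#' log-spaced spatial frequencies (1.5-24 cycles/image), temporal frequencies
#' 0, 1.33 and 2.667 Hz, eight motion directions in 45-degree steps (four
#' orientations for the static, zero-temporal-frequency filters), plus one
#' zero-spatial-frequency (pure Gaussian) filter. The spatial envelope SD is
#' \code{cyclesPerSD} wavelengths, capped at \code{maxSpatialSD} image widths;
#' adjacent filters of the same parameters are separated by \code{spacingSD}
#' spatial SDs, with as many filters per axis as fit
#' (\code{n = max(1, ceiling(1 / spacing))}, lattice centered on the image).
#' Each listed filter is realised at both quadrature phases (0 and 90 deg)
#' when applied; by default a quadrature pair counts as one filter, set
#' \code{countPhases = TRUE} to enumerate phases as separate rows.
#'
#' @param imageSize frame side length in pixels.
#' @param spatialFreqs spatial frequencies, cycles/image.
#' @param temporalFreqs temporal frequencies, Hz.
#' @param directions motion directions, degrees.
#' @param staticDirections orientations used when temporal frequency is 0.
#' @param cyclesPerSD spatial envelope SD in wavelengths.
#' @param maxSpatialSD envelope SD cap, image fractions.
#' @param spacingSD center-to-center spacing in spatial SDs.
#' @param windowFrames temporal integration window (frames).
#' @param frameRate video frame rate (Hz).
#' @param countPhases enumerate the two quadrature phases as separate rows.
#' @return a \linkS4class{GaborBank}.
#' @export
buildGaborBank <- function(imageSize = 96,
                           spatialFreqs = c(1.5, 3, 6, 12, 24),
                           temporalFreqs = c(0, 4 / 3, 8 / 3),
                           directions = seq(0, 315, by = 45),
                           staticDirections = c(0, 45, 90, 135),
                           cyclesPerSD = 0.6, maxSpatialSD = 0.3,
                           spacingSD = 4, windowFrames = 10, frameRate = 24,
                           countPhases = FALSE) {
  if (spacingSD <= 0 || cyclesPerSD <= 0 || maxSpatialSD <= 0)
    stop("spacing and envelope parameters must be positive")
  rows <- list()
  for (sf in spatialFreqs) {
    sigma <- min(cyclesPerSD / sf, maxSpatialSD)
    delta <- spacingSD * sigma
    n <- max(1L, ceiling(1 / delta - 1e-9))
    centers <- 0.5 + (seq_len(n) - (n + 1) / 2) * delta
    grid <- expand.grid(cx = centers, cy = centers)
    for (tf in temporalFreqs) {
      dirs <- if (tf == 0) staticDirections else directions
      for (dir in dirs) {
        rows[[length(rows) + 1L]] <- data.frame(
          sf = sf, tf = tf, dir = dir, cx = grid$cx, cy = grid$cy,
          sigmaS = sigma, sigmaT = windowFrames / 4, type = "gabor")
      }
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sf = 0, tf = 0, dir = 0, cx = 0.5, cy = 0.5,
    sigmaS = maxSpatialSD, sigmaT = windowFrames / 4, type = "gaussian")
  filters <- do.call(rbind, rows)
  filters <- filters[order(filters$sf != 0, filters$sf, filters$tf,
                           filters$dir, filters$cy, filters$cx), ]
  rownames(filters) <- NULL
  if (countPhases) {
    filters <- filters[rep(seq_len(nrow(filters)),
                           ifelse(filters$type == "gabor", 2L, 1L)), ]
    filters$phase <- 0
    dup <- duplicated(filters[setdiff(names(filters), "phase")])
    filters$phase[dup] <- 90
    rownames(filters) <- NULL
  }
  new("GaborBank", filters = filters,
      params = list(imageSize = imageSize, spatialFreqs = spatialFreqs,
                    temporalFreqs = temporalFreqs, directions = directions,
                    staticDirections = staticDirections,
                    cyclesPerSD = cyclesPerSD, maxSpatialSD = maxSpatialSD,
                    spacingSD = spacingSD, windowFrames = windowFrames,
                    frameRate = frameRate, countPhases = countPhases))
}

# Centered convolution with zero padding; kernel of any length.
.convCentered <- function(x, k) {
  L <- length(k)
  lp <- floor((L - 1) / 2)
  fftConv(x, k)[(lp + 1L):(lp + length(x))]
}

# Build the sparse (2 * nFilters) x nPixels spatial kernel matrix: for each
# quadrature pair, a DC-free even (cosine) and odd (sine) kernel, unit L2
# norm, truncated to a +/- 4 SD support box.
.spatialKernels <- function(filters, imageSize) {
  px <- (seq_len(imageSize) - 0.5) / imageSize
  ii <- list(); jj <- list(); vv <- list()
  for (f in seq_len(nrow(filters))) {
    sf <- filters$sf[f]; sigma <- filters$sigmaS[f]
    cx <- filters$cx[f]; cy <- filters$cy[f]
    th <- filters$dir[f] * pi / 180
    half <- 4 * sigma
    xs <- which(px >= cx - half & px <= cx + half)
    ys <- which(px >= cy - half & px <= cy + half)
    if (!length(xs)) xs <- seq_len(imageSize)
    if (!length(ys)) ys <- seq_len(imageSize)
    dx <- px[xs] - cx; dy <- px[ys] - cy
    G <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))   # rows = y, cols = x
    if (filters$type[f] == "gaussian" || sf == 0) {
      even <- G / sqrt(sum(G^2))
      odd <- G * 0
    } else {
      phase <- 2 * pi * sf * outer(sin(th) * dy, cos(th) * dx, "+")
      even <- G * cos(phase); odd <- G * sin(phase)
      # exact DC removal so energy is invariant to global luminance offsets
      even <- even - sum(even) / length(even)
      odd <- odd - sum(odd) / length(odd)
      ne <- sqrt(sum(even^2)); no <- sqrt(sum(odd^2))
      if (ne > 0) even <- even / ne
      if (no > 0) odd <- odd / no
    }
    # pixel linear indices (row-major within the y/x subgrid)
    pix <- as.vector(outer(ys, (xs - 1L) * imageSize, "+"))
    ii[[f]] <- c(rep(2L * f - 1L, length(pix)), rep(2L * f, length(pix)))
    jj[[f]] <- c(pix, pix)
    vv[[f]] <- c(as.vector(even), as.vector(odd))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(2L * nrow(filters), imageSize^2))
}

#' Motion energy of a luminance movie under a Gabor bank
#'
#' For each quadrature pair, the spatiotemporal responses of the 0- and
#' 90-degree phases over a sliding \code{windowFrames}-frame window are
#' combined into the phase-invariant energy \code{sqrt(r0^2 + r90^2)},
#' log-transformed as \code{log(1 + E)}, and resampled from the frame rate to
#' \code{outRate}.
#'
#' @param frames luminance array (size x size x T in [0, 1]), e.g. from
#'   \code{\link{preprocessFrames}}.
#' @param bank a \linkS4class{GaborBank}.
#' @param outRate output sampling rate (128).
#' @param upsample "linear" interpolation (default) or "nearest" frame.
#' @return a \linkS4class{FeatureStream} with one column per quadrature pair.
#' @export
motionEnergy <- function(frames, bank, outRate = 128,
                         upsample = c("linear", "nearest")) {
  upsample <- match.arg(upsample)
  p <- bank@params
  filters <- filterTable(bank)
  if (isTRUE(p$countPhases))
    filters <- filters[is.null(filters$phase) | filters$phase == 0, ]
  d <- dim(frames)
  if (length(d) != 3L || d[1] != p$imageSize || d[2] != p$imageSize)
    stop("frames must be ", p$imageSize, " x ", p$imageSize, " x T")
  nT <- d[3]
  if (nT < p$windowFrames)
    stop("need at least ", p$windowFrames, " frames")
  W <- .spatialKernels(filters, p$imageSize)
  F <- matrix(frames, p$imageSize^2, nT)
  R <- as.matrix(W %*% F)                      # (2 nFilt) x T
  w <- p$windowFrames
  tc0 <- seq_len(w) - (w + 1) / 2
  env <- exp(-tc0^2 / (2 * (w / 4)^2))
  E <- matrix(0, nT, nrow(filters))
  for (tf in unique(filters$tf)) {
    idx <- which(filters$tf == tf)
    ftf <- tf / p$frameRate                    # cycles per frame
    tc <- env * cos(2 * pi * ftf * tc0)
    # convolution time-reverses the kernel; negate the odd part so the
    # quadrature combination prefers motion toward the filter's direction
    ts <- -env * sin(2 * pi * ftf * tc0)
    for (f in idx) {
      A <- R[2L * f - 1L, ]; B <- R[2L * f, ]
      rEven <- .convCentered(A, tc) + .convCentered(B, ts)
      rOdd <- .convCentered(B, tc) - .convCentered(A, ts)
      E[, f] <- sqrt(rEven^2 + rOdd^2)
    }
  }
  E <- log1p(E)
  nOut <- round(nT / p$frameRate * outRate)
  tIn <- (seq_len(nT) - 0.5) / p$frameRate
  tOut <- (seq_len(nOut) - 0.5) / outRate
  up <- apply(E, 2L, function(col)
    stats::approx(tIn, col, xout = tOut, rule = 2,
                  method = if (upsample == "linear") "linear" else "constant")$y)
  FeatureStream(up, sprintf("gabor_%04d", seq_len(nrow(filters))), "visual",
                outRate)
}

#' Reduce motion-energy features to principal components
#'
#' Fits a column-centered PCA on training data only and projects onto the top
#' \code{k} components; the returned projection is reused verbatim for test
#' data via \code{\link{applyPcaProjection}}.
#'
#' @param energies a \linkS4class{FeatureStream} of filter energies.
#' @param k number of components (10).
#' @return list with \code{stream} (k-column \linkS4class{FeatureStream}) and
#'   \code{projection} (center + rotation).
#' @export
pcaReduce <- function(energies, k = 10) {
  x <- streamData(energies)
  if (k > ncol(x)) stop("k exceeds the number of features")
  if (nrow(x) <= k) stop("need more time samples than components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  proj <- list(center = pc$center, rotation = pc$rotation,
               sdev = pc$sdev)
  list(stream = FeatureStream(pc$x[, seq_len(k), drop = FALSE],
                              paste0("gaborPC", seq_len(k)), "visual",
                              sampleRate(energies)),
       projection = proj)
}

#' @rdname pcaReduce
#' @param stream a \linkS4class{FeatureStream} with the same filter columns.
#' @param projection the projection returned by \code{pcaReduce}.
#' @export
applyPcaProjection <- function(stream, projection) {
  x <- streamData(stream)
  if (ncol(x) != length(projection$center))
    stop("feature count does not match the fitted projection")
  sc <- sweep(x, 2L, projection$center) %*% projection$rotation
  FeatureStream(sc, colnames(projection$rotation), "visual",
                sampleRate(stream))
}

#' Scene-cut impulse vector
#'
#' A 1 at the sample nearest each scene-change onset in the scene tier,
#' 0 elsewhere.
#'
#' @param annot an \linkS4class{AnnotationTrack} with a scene tier.
#' @param duration stream duration in seconds.
#' @param tier tier name.
#' @param rate output rate.
#' @return a one-column binary \linkS4class{FeatureStream}.
#' @export
sceneCutVector <- function(annot, duration, tier = "scene", rate = 128) {
  tl <- tiers(annot)
  if (!tier %in% names(tl)) stop("annotation has no '", tier, "' tier")
  cuts <- tl[[tier]]$start
  if (length(cuts) && max(cuts) > duration)
    stop("scene-cut onset beyond the requested duration")
  nSamp <- round(duration * rate)
  v <- numeric(nSamp)
  v[pmin(nSamp, round(cuts * rate) + 1L)] <- 1
  FeatureStream(matrix(v, ncol = 1), "scene_cut", "visual", rate)
}
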