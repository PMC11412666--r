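# High-level driver: fit one feature family across several stimulation
# conditions that share the same stimulus. The delay-embedded design is
# built once and kept in raw form; column standardization is applied
# algebraically to the Gram matrix and cross-products rather than to the
# data, so no design-sized copy is ever made. This is the memory- and
# time-efficient path for whole-study analyses; trainTRF / shuffleTest
# remain the single-model building blocks.

#' Fit and evaluate one feature family across stimulus conditions
#'
#' All conditions share the stimulus (the feature streams of the same
#' trailers), so the expensive objects — the delay-embedded design, its
#' Gram matrix and eigendecomposition — are built once and reused for the
#' cross-validated lambda search, the final ridge solves, evaluation on the
#' held-out stimulus, and the chunk-shuffle significance test. Standardizing
#' the design columns is folded into the normal equations:
#' with D the diagonal of column SDs and m the column means, the
#' standardized Gram is D^-1 (S'S - n m m') D^-1, window Grams and
#' cross-products transform likewise, and the constant term cancels in every
#' correlation, so the raw design matrix is used unmodified throughout.
#'
#' @param stimTrain training stimulus (\linkS4class{FeatureStream} or named
#'   matrix), concatenated over training trailers.
#' @param respTrain named list of training response matrices
#'   (time x channels), one per condition, aligned to \code{stimTrain}.
#' @param stimTest held-out stimulus.
#' @param respTest held-out response matrix (time x channels) against which
#'   every condition's model is scored (e.g. the unimodal test EEG for a
#'   within/cross comparison).
#' @param lags integer sample lags.
#' @param lambdaGrid,nIter,seed lambda search controls (see
#'   \code{\link{cvLambda}}).
#' @param trainFrac fraction of samples fit on within each search split.
#' @param nShuffles if > 0, run the chunk-shuffle test for the conditions in
#'   \code{shuffleFor}.
#' @param shuffleFor condition names to shuffle-test (default: the first).
#' @param chunkSec shuffle chunk length in seconds.
#' @param rate sampling rate (128).
#' @param standardize z-score design columns and responses with training
#'   statistics.
#' @param trainTrailers provenance recorded on the models.
#' @return list with \code{models} (named list of \linkS4class{TRFModel}),
#'   \code{evals} (named list of \linkS4class{EvalResult}; p-values and a
#'   \code{"nullR"} attribute present where the shuffle test ran) and
#'   \code{lambda} (the per-channel selections).
#' @export
runConditionAnalysis <- function(stimTrain, respTrain, stimTest, respTest,
                                 lags = defaultLags(),
                                 lambdaGrid = logspace(1e2, 1e8, 15),
                                 nIter = 20, seed = 0, trainFrac = 0.8,
                                 nShuffles = 0,
                                 shuffleFor = names(respTrain)[1],
                                 chunkSec = 2, rate = 128,
                                 standardize = TRUE,
                                 trainTrailers = character()) {
  stopifnot(is.list(respTrain), !is.null(names(respTrain)))
  x <- .streamMatrix(stimTrain)
  fn <- if (is(stimTrain, "FeatureStream")) featureNames(stimTrain) else
    (colnames(x) %||% paste0("f", seq_len(ncol(x))))
  respTrain <- lapply(respTrain, .responseMatrix)
  yt <- .responseMatrix(respTest)
  chLabels <- colnames(respTrain[[1]]) %||%
    paste0("ch", seq_len(ncol(respTrain[[1]])))
  lambdaGrid <- sort(lambdaGrid)
  S <- delayEmbed(x, lags)
  St <- delayEmbed(.streamMatrix(stimTest), lags)
  nT <- nrow(S); p <- ncol(S)
  G <- crossprod(S)
  m <- colMeans(S)
  if (standardize) {
    sx <- sqrt(pmax(diag(G) - nT * m^2, 0) / (nT - 1))
    sx[sx == 0 | !is.finite(sx)] <- 1
    syList <- lapply(respTrain, zscoreFit)
    respTrain <- Map(zscoreApply, respTrain, syList)  # responses are small
  } else {
    m <- numeric(p); sx <- rep(1, p)
    syList <- lapply(respTrain, function(y)
      list(center = numeric(0), scale = numeric(0)))
  }
  # standardized Gram and cross-products, from the raw ones
  Gz <- (G - nT * tcrossprod(m)) / tcrossprod(sx)
  Cz <- lapply(respTrain, function(yz) crossprod(S, yz) / sx)
  rm(G); gc(FALSE)

  # ---- cross-validated lambda search on contiguous 80/20 splits ----
  wLen <- floor((1 - trainFrac) * nT)
  if (wLen < 2L * max(lags) + 16L)
    stop("training data too short for the held-out split")
  acc <- lapply(respTrain, function(yz)
    matrix(0, length(lambdaGrid), ncol(yz)))
  set.seed(seed)
  starts <- sample.int(nT - wLen + 1L, nIter, replace = TRUE)
  for (it in seq_len(nIter)) {
    win <- starts[it]:(starts[it] + wLen - 1L)
    Sw <- S[win, , drop = FALSE]
    sw <- colSums(Sw)
    Gwz <- (crossprod(Sw) - outer(m, sw) - outer(sw, m) +
              wLen * tcrossprod(m)) / tcrossprod(sx)
    eg <- eigen(Gz - Gwz, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    for (cond in names(respTrain)) {
      yzw <- respTrain[[cond]][win, , drop = FALSE]
      Cwz <- (crossprod(Sw, yzw) - outer(m, colSums(yzw))) / sx
      VC <- crossprod(eg$vectors, Cz[[cond]] - Cwz)
      for (li in seq_along(lambdaGrid)) {
        W <- eg$vectors %*% (VC / (d + lambdaGrid[li]))
        # constant offsets cancel in the correlation, so the raw window
        # design can score the standardized-space weights directly
        r <- colCorr(Sw %*% (W / sx), yzw, warn = FALSE)
        acc[[cond]][li, ] <- acc[[cond]][li, ] + r / nIter
      }
    }
    rm(Sw, Gwz, eg)
    gc(FALSE)
  }
  lam <- lapply(acc, function(curve) {
    l <- lambdaGrid[apply(curve, 2L, which.max)]
    attr(l, "cvCurve") <- curve
    l
  })

  # ---- final fits, evaluation, shuffle null ----
  eg <- eigen(Gz, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  gc(FALSE)
  chunk <- round(chunkSec * rate)
  blocks <- split(seq_len(nT), rep(seq_len(ceiling(nT / chunk)),
                                   each = chunk)[seq_len(nT)])
  nL <- length(lags); nF <- ncol(x)
  models <- list(); evals <- list()
  for (cond in names(respTrain)) {
    yz <- respTrain[[cond]]
    lamVec <- as.numeric(lam[[cond]])
    W <- .ridgeFromEig(eg$vectors, d, Cz[[cond]], lamVec)
    weights <- aperm(array(W, c(nL, nF, ncol(yz))), c(2, 1, 3))
    sy <- syList[[cond]]
    models[[cond]] <- new("TRFModel", weights = weights, lambda = lamVec,
                          lags = as.integer(lags), rate = rate,
                          featureNames = fn, channelLabels = chLabels,
                          trainTrailers = as.character(trainTrailers),
                          condition = cond,
                          featureCenter = if (standardize) m else numeric(0),
                          featureScale = if (standardize) sx else numeric(0),
                          responseCenter = sy$center,
                          responseScale = sy$scale)
    rObs <- colCorr(St %*% (W / sx), yt, warn = FALSE)
    ev <- new("EvalResult", r = rObs, p = rep(NA_real_, length(rObs)),
              nTestSamples = nrow(yt), modelTag = cond,
              channelLabels = chLabels)
    if (nShuffles > 0 && cond %in% shuffleFor) {
      set.seed(childSeed(seed, 17 + match(cond, names(respTrain))))
      nullR <- matrix(0, nShuffles, ncol(yz))
      for (s in seq_len(nShuffles)) {
        perm <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
        # the permuted response is centered, so its cross-product
        # standardizes with the same diagonal scaling alone
        Cs <- crossprod(S, yz[perm, , drop = FALSE]) / sx
        Ws <- .ridgeFromEig(eg$vectors, d, Cs, lamVec)
        nullR[s, ] <- colCorr(St %*% (Ws / sx), yt, warn = FALSE)
        if (s %% 5 == 0) gc(FALSE)
      }
      ev@p <- (1 + colSums(sweep(nullR, 2L, rObs, ">="))) / (1 + nShuffles)
      attr(ev, "nullR") <- nullR
    }
    evals[[cond]] <- ev
    gc(FALSE)
  }
  list(models = models, evals = evals, lambda = lam)
}
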