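# Delay-embedded ridge-regression temporal response functions: design
# construction, closed-form ridge solves, regularization search, prediction,
# scoring, chunk-shuffle significance, trailer-level data splits.

#' Default delay grid: 0-600 ms at 128 Hz
#'
#' 77 integer sample lags, 0..76 (0 to 593.75 ms).
#' @return integer vector of lags.
#' @export
defaultLags <- function() 0:76

.streamMatrix <- function(stim) {
  if (is(stim, "FeatureStream")) streamData(stim) else as.matrix(stim)
}

.responseMatrix <- function(resp) {
  if (is(resp, "EEGEpoch")) t(epochData(resp)) else as.matrix(resp)
}

#' Delay-embed a stimulus into a design matrix
#'
#' Column (f, tau) at row t holds \code{stim[t - tau, f]}; out-of-range
#' entries are 0. Columns are ordered feature-major, lag-minor: all lags of
#' feature 1, then all lags of feature 2, ...
#'
#' @param stim a \linkS4class{FeatureStream} or (time x features) matrix.
#' @param lags non-negative integer sample lags.
#' @return time x (features * lags) matrix.
#' @export
delayEmbed <- function(stim, lags = defaultLags()) {
  x <- .streamMatrix(stim)
  if (!nrow(x)) stop("empty stimulus")
  if (nrow(x) <= max(lags)) stop("stimulus shorter than the maximum lag")
  nT <- nrow(x); nF <- ncol(x); nL <- length(lags)
  out <- matrix(0, nT, nF * nL)
  for (f in seq_len(nF)) {
    for (l in seq_len(nL)) {
      tau <- lags[l]
      col <- (f - 1L) * nL + l
      if (tau == 0L) out[, col] <- x[, f]
      else out[(tau + 1L):nT, col] <- x[seq_len(nT - tau), f]
    }
  }
  cn <- colnames(x)
  if (!is.null(cn))
    colnames(out) <- paste0(rep(cn, each = nL), "_lag", rep(lags, nF))
  out
}

#' Closed-form ridge solution
#'
#' Solves \code{(S'S + lambda I) W = S'Y} by Cholesky factorization (solved,
#' never inverted). \code{lambda} may be a scalar or one value per response
#' column.
#'
#' @param design time x predictors matrix.
#' @param response time x channels matrix.
#' @param lambda ridge penalty (>= 0).
#' @return predictors x channels weight matrix.
#' @export
ridgeFit <- function(design, response, lambda) {
  response <- as.matrix(response)
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (any(!is.finite(design)) || any(!is.finite(response)))
    stop("non-finite values in design or response")
  G <- crossprod(design)
  C <- crossprod(design, response)
  p <- ncol(design)
  solveOne <- function(lam, cc) {
    ch <- tryCatch(chol(G + diag(lam, p)), error = function(e) NULL)
    if (is.null(ch))
      stop("normal equations are singular; use lambda > 0")
    backsolve(ch, forwardsolve(t(ch), cc))
  }
  if (length(lambda) == 1L) return(solveOne(lambda, C))
  if (length(lambda) != ncol(response))
    stop("lambda must be scalar or one value per channel")
  W <- matrix(0, p, ncol(response))
  for (lam in unique(lambda)) {
    idx <- which(lambda == lam)
    W[, idx] <- solveOne(lam, C[, idx, drop = FALSE])
  }
  W
}

# Eigendecomposition-based ridge weights for a fixed factorization:
# W = V diag(1/(d + lambda)) V' C, grouped over unique lambdas.
.ridgeFromEig <- function(V, d, C, lambda) {
  if (length(lambda) == 1L)
    return(V %*% (crossprod(V, C) / (d + lambda)))
  W <- matrix(0, nrow(V), ncol(C))
  VC <- crossprod(V, C)
  for (lam in unique(lambda)) {
    idx <- which(lambda == lam)
    W[, idx] <- V %*% (VC[, idx, drop = FALSE] / (d + lam))
  }
  W
}

#' Cross-validated ridge-parameter search
#'
#' For each of \code{nIter} iterations a random contiguous 80/20 split of the
#' training time axis is drawn; for every lambda on the grid the model is fit
#' on the 80\% and scored (Pearson r) on the held-out 20\%. Each channel gets
#' the lambda maximizing its mean held-out correlation across iterations
#' (ties resolved toward the smallest lambda).
#'
#' @param stim training stimulus (\linkS4class{FeatureStream} or matrix).
#' @param resp training response matrix (time x channels), or a named list of
#'   such matrices sharing the stimulus (the expensive per-split
#'   factorizations are then shared).
#' @param lags integer sample lags.
#' @param lambdaGrid candidate penalties (default 15 log-spaced values,
#'   1e2..1e8).
#' @param nIter number of random splits (20).
#' @param trainFrac fraction of samples used for fitting within each split.
#' @param seed RNG seed.
#' @param standardize z-score stimulus/response columns before the search.
#' @return per-channel lambda vector (or named list, matching \code{resp});
#'   the mean CV correlation curves are attached as attribute
#'   \code{"cvCurve"} (lambda x channel).
#' @export
cvLambda <- function(stim, resp, lags = defaultLags(),
                     lambdaGrid = logspace(1e2, 1e8, 15), nIter = 20,
                     trainFrac = 0.8, seed = 0, standardize = TRUE) {
  single <- !is.list(resp)
  respList <- if (single) list(resp) else resp
  respList <- lapply(respList, .responseMatrix)
  if (isTRUE(attr(stim, "alreadyEmbedded"))) {
    S <- unclass(stim)
  } else {
    S <- delayEmbed(.streamMatrix(stim), lags)
    if (standardize) {
      S <- zscoreApply(S, zscoreFit(S))
      respList <- lapply(respList, function(y) zscoreApply(y, zscoreFit(y)))
    }
  }
  nT <- nrow(S)
  wLen <- floor((1 - trainFrac) * nT)
  if (wLen < 2L * max(lags) + 16L)
    stop("training data too short for a ", round(100 * (1 - trainFrac)),
         "% held-out split")
  lambdaGrid <- sort(lambdaGrid)
  G <- crossprod(S)
  Cfull <- lapply(respList, function(y) crossprod(S, y))
  acc <- lapply(respList, function(y)
    array(0, c(length(lambdaGrid), ncol(y))))
  set.seed(seed)
  starts <- sample.int(nT - wLen + 1L, nIter, replace = TRUE)
  for (it in seq_len(nIter)) {
    win <- starts[it]:(starts[it] + wLen - 1L)
    Sw <- S[win, , drop = FALSE]
    Gtr <- G - crossprod(Sw)
    eg <- eigen(Gtr, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    for (j in seq_along(respList)) {
      Yw <- respList[[j]][win, , drop = FALSE]
      Ctr <- Cfull[[j]] - crossprod(Sw, Yw)
      VC <- crossprod(eg$vectors, Ctr)
      for (li in seq_along(lambdaGrid)) {
        W <- eg$vectors %*% (VC / (d + lambdaGrid[li]))
        r <- colCorr(Sw %*% W, Yw, warn = FALSE)
        acc[[j]][li, ] <- acc[[j]][li, ] + r / nIter
      }
    }
    rm(Sw, Gtr, eg)
    gc(FALSE)  # keep per-split temporaries from accumulating
  }
  pick <- function(curve) {
    lam <- lambdaGrid[apply(curve, 2L, which.max)]
    attr(lam, "cvCurve") <- curve
    lam
  }
  out <- lapply(acc, pick)
  if (single) out[[1]] else out
}

#' Fit a temporal response function model
#'
#' Optionally z-scores stimulus and response columns (training statistics are
#' stored on the model and reused for prediction), runs the cross-validated
#' lambda search unless \code{lambda} is supplied, and solves the ridge
#' normal equations on the full training set.
#'
#' @param stim training stimulus (\linkS4class{FeatureStream} or named
#'   matrix).
#' @param resp training response: time x channels matrix or
#'   \linkS4class{EEGEpoch}.
#' @param lags integer sample lags (default 0..76 at 128 Hz).
#' @param lambda optional per-channel or scalar penalty; when NULL,
#'   \code{\link{cvLambda}} selects it.
#' @param lambdaGrid,nIter,seed passed to \code{\link{cvLambda}}.
#' @param standardize z-score columns using training statistics.
#' @param trainTrailers,condition provenance recorded on the model.
#' @param channelNames channel labels (taken from \code{resp} if available).
#' @param rate sampling rate of stimulus/response (128).
#' @return a \linkS4class{TRFModel}.
#' @export
trainTRF <- function(stim, resp, lags = defaultLags(), lambda = NULL,
                     lambdaGrid = logspace(1e2, 1e8, 15), nIter = 20,
                     seed = 0, standardize = TRUE,
                     trainTrailers = character(), condition = "AV",
                     channelNames = NULL, rate = 128) {
  x <- .streamMatrix(stim)
  fn <- if (is(stim, "FeatureStream")) featureNames(stim) else
    (colnames(x) %||% paste0("f", seq_len(ncol(x))))
  if (is.null(channelNames))
    channelNames <- if (is(resp, "EEGEpoch")) channelLabels(resp) else
      (colnames(.responseMatrix(resp)) %||%
         paste0("ch", seq_len(ncol(.responseMatrix(resp)))))
  y <- .responseMatrix(resp)
  if (nrow(x) != nrow(y))
    stop("stimulus and response lengths differ (", nrow(x), " vs ",
         nrow(y), ")")
  S <- delayEmbed(x, lags)
  if (standardize) {
    # standardization acts on the embedded design columns so that the
    # fitted linear map stays exactly consistent with lag-domain generation
    sx <- zscoreFit(S); sy <- zscoreFit(y)
    S <- zscoreApply(S, sx); y <- zscoreApply(y, sy)
  } else {
    sx <- list(center = numeric(0), scale = numeric(0))
    sy <- list(center = numeric(0), scale = numeric(0))
  }
  if (is.null(lambda))
    lambda <- as.numeric(cvLambda(.embedded(S), y, lags, lambdaGrid, nIter,
                                  seed = seed, standardize = FALSE))
  if (length(lambda) == 1L) lambda <- rep(lambda, ncol(y))
  W <- ridgeFit(S, y, lambda)
  nL <- length(lags)
  weights <- array(W, c(nL, ncol(x), ncol(y)))    # lag-fastest from flat
  weights <- aperm(weights, c(2, 1, 3))           # features x lags x channels
  new("TRFModel", weights = weights, lambda = lambda,
      lags = as.integer(lags), rate = rate, featureNames = fn,
      channelLabels = channelNames,
      trainTrailers = as.character(trainTrailers), condition = condition,
      featureCenter = sx$center, featureScale = sx$scale,
      responseCenter = sy$center, responseScale = sy$scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tag a matrix as an already-embedded (and standardized) design so that
# cvLambda skips its own embedding.
.embedded <- function(S) {
  attr(S, "alreadyEmbedded") <- TRUE
  S
}

#' Predict EEG from a fitted model
#'
#' Computes \code{yhat(t, n) = sum_f sum_tau w(f, tau, n) s(f, t - tau)} on
#' the model's scale, then maps back to native response units when the model
#' was fit with standardization.
#'
#' @param model a \linkS4class{TRFModel}.
#' @param stim a \linkS4class{FeatureStream} or named matrix; feature names
#'   must match the model's, in order.
#' @return time x channels matrix of predictions.
#' @export
predictResponse <- function(model, stim) {
  x <- .streamMatrix(stim)
  fn <- if (is(stim, "FeatureStream")) featureNames(stim) else colnames(x)
  if (!is.null(fn) && !identical(fn, model@featureNames)) {
    diffs <- c(setdiff(model@featureNames, fn), setdiff(fn, model@featureNames))
    if (length(diffs) || !identical(fn, model@featureNames))
      stop("feature names do not match the model (differences: ",
           paste(unique(c(diffs, "order")), collapse = ", "), ")")
  }
  if (ncol(x) != dim(model@weights)[1]) stop("feature count mismatch")
  S <- delayEmbed(x, model@lags)
  if (length(model@featureScale))
    S <- zscoreApply(S, list(center = model@featureCenter,
                             scale = model@featureScale))
  W <- matrix(aperm(model@weights, c(2, 1, 3)),
              nrow = dim(model@weights)[1] * dim(model@weights)[2])
  pred <- S %*% W
  if (length(model@responseScale))
    pred <- sweep(sweep(pred, 2L, model@responseScale, "*"), 2L,
                  model@responseCenter, "+")
  colnames(pred) <- model@channelLabels
  pred
}

#' Per-channel prediction accuracy
#'
#' Pearson correlation between predicted and actual responses, per channel;
#' zero-variance channels yield r = 0 with a warning.
#'
#' @param pred,actual time x channels matrices (or \linkS4class{EEGEpoch}).
#' @return numeric vector of correlations.
#' @export
scoreChannels <- function(pred, actual) {
  colCorr(.responseMatrix(pred), .responseMatrix(actual))
}

#' Evaluate a model on held-out data
#'
#' @param model a \linkS4class{TRFModel}.
#' @param stimTest,respTest held-out stimulus and response.
#' @param modelTag label stored on the result.
#' @return an \linkS4class{EvalResult} (p = NA; see
#'   \code{\link{shuffleTest}}).
#' @export
evaluateTRF <- function(model, stimTest, respTest, modelTag = "model") {
  y <- .responseMatrix(respTest)
  r <- scoreChannels(predictResponse(model, stimTest), y)
  new("EvalResult", r = r, p = rep(NA_real_, length(r)),
      nTestSamples = nrow(y), modelTag = modelTag,
      channelLabels = model@channelLabels)
}

#' Chunk-shuffle significance test
#'
#' Breaks the stimulus-response relationship by cutting the training time
#' axis into 2-s chunks (final partial chunk kept) and permuting the pairing
#' between the delay-embedded stimulus and the response chunks, refitting the
#' ridge model at the same lambda, and re-scoring the held-out test set. The
#' permutation leaves the design Gram matrix unchanged, so the refits reuse a
#' single eigendecomposition. The add-one estimator
#' p = (1 + #\{r_null >= r_obs\}) / (1 + nShuffles) avoids p = 0.
#'
#' @param stimTrain,respTrain training stimulus and response.
#' @param stimTest,respTest held-out test stimulus and response.
#' @param lags integer sample lags.
#' @param lambda scalar or per-channel ridge penalty (e.g. from a fitted
#'   model's \code{lambdaValues}).
#' @param nShuffles number of permutations (100).
#' @param chunkSec chunk length in seconds (2).
#' @param rate sampling rate (128).
#' @param seed RNG seed.
#' @param standardize z-score with training statistics, as in
#'   \code{\link{trainTRF}}.
#' @param modelTag label for the result.
#' @return an \linkS4class{EvalResult} with permutation p-values; the null
#'   correlations are attached as attribute \code{"nullR"}
#'   (nShuffles x channels).
#' @export
shuffleTest <- function(stimTrain, respTrain, stimTest, respTest,
                        lags = defaultLags(), lambda, nShuffles = 100,
                        chunkSec = 2, rate = 128, seed = 0,
                        standardize = TRUE, modelTag = "shuffle") {
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  x <- .streamMatrix(stimTrain); y <- .responseMatrix(respTrain)
  xt <- .streamMatrix(stimTest); yt <- .responseMatrix(respTest)
  S <- delayEmbed(x, lags)
  St <- delayEmbed(xt, lags)
  if (standardize) {
    sx <- zscoreFit(S); sy <- zscoreFit(y)
    S <- zscoreApply(S, sx); St <- zscoreApply(St, sx)
    y <- zscoreApply(y, sy); yt <- zscoreApply(yt, sy)
    gc(FALSE)
  }
  chunk <- round(chunkSec * rate)
  nT <- nrow(S)
  nChunks <- ceiling(nT / chunk)
  if (nChunks < 3L) stop("training data shorter than 3 shuffle chunks")
  G <- crossprod(S)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (length(lambda) == 1L) lambda <- rep(lambda, ncol(y))
  fitScore <- function(Y) {
    W <- .ridgeFromEig(eg$vectors, d, crossprod(S, Y), lambda)
    colCorr(St %*% W, yt, warn = FALSE)
  }
  rObs <- fitScore(y)
  blocks <- split(seq_len(nT), rep(seq_len(nChunks), each = chunk)[seq_len(nT)])
  set.seed(seed)
  nullR <- matrix(0, nShuffles, ncol(y))
  for (s in seq_len(nShuffles)) {
    perm <- unlist(blocks[sample.int(nChunks)], use.names = FALSE)
    nullR[s, ] <- fitScore(y[perm, , drop = FALSE])
    if (s %% 5 == 0) gc(FALSE)
  }
  p <- (1 + colSums(sweep(nullR, 2L, rObs, ">="))) / (1 + nShuffles)
  res <- new("EvalResult", r = rObs, p = p, nTestSamples = nrow(yt),
             modelTag = modelTag,
             channelLabels = colnames(y) %||% paste0("ch", seq_len(ncol(y))))
  attr(res, "nullR") <- nullR
  res
}

#' Deterministic train/test partition by trailer
#'
#' @param trailerIds available trailer ids (character vector), or a
#'   \linkS4class{SimulatedDataset}.
#' @param testIds trailer ids forming the test set.
#' @return list with \code{train} and \code{test} id vectors.
#' @export
splitByTrailer <- function(trailerIds, testIds) {
  if (is(trailerIds, "SimulatedDataset"))
    trailerIds <- names(trailerIds@features)
  testIds <- as.character(testIds)
  if (!length(testIds)) stop("test set is empty")
  unknown <- setdiff(testIds, trailerIds)
  if (length(unknown))
    stop("unknown trailer id(s): ", paste(unknown, collapse = ", "))
  train <- setdiff(trailerIds, testIds)
  if (!length(train)) stop("training set is empty (all trailers held out)")
  list(train = train, test = unique(testIds))
}

#' Concatenate feature streams or epochs along time
#'
#' @param streams list of \linkS4class{FeatureStream}s with identical
#'   features.
#' @return one \linkS4class{FeatureStream}.
#' @export
concatenateStreams <- function(streams) {
  stopifnot(length(streams) >= 1)
  fn <- featureNames(streams[[1]])
  for (s in streams) stopifnot(identical(featureNames(s), fn))
  FeatureStream(do.call(rbind, lapply(streams, streamData)), fn,
                modality(streams[[1]]), sampleRate(streams[[1]]))
}

#' @rdname concatenateStreams
#' @param epochs list of \linkS4class{EEGEpoch}s with identical channels.
#' @return time x channels response matrix.
#' @export
concatenateEpochs <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  labs <- channelLabels(epochs[[1]])
  for (e in epochs) stopifnot(identical(channelLabels(e), labs))
  y <- do.call(rbind, lapply(epochs, function(e) t(epochData(e))))
  colnames(y) <- labs
  y
}
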