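# Cross-condition analyses: within- vs cross-condition prediction, weight
# correlation topographies, inter-condition EEG correlation, ROI summaries.

#' Standard 64-channel 10-20 montage labels
#'
#' The EasyCap-style extended 10-20 layout used throughout the package
#' (includes the mastoids TP9/TP10).
#' @return character vector of 64 labels.
#' @export
defaultMontage64 <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
}

#' Assign scalp channels to regions of interest
#'
#' Prefix-based assignment from 10-20 labels: Fp/AF/F -> frontal; FC/C ->
#' central; CP/P -> parietal; PO/O/I -> occipital; T/FT/TP -> temporal.
#' Boundary labels resolve by their leading letter block (e.g. FCz ->
#' central, FT8 -> temporal). Override any channel via \code{overrides}.
#'
#' @param labels channel label vector.
#' @param overrides named character vector, label -> roi.
#' @return named character vector label -> roi.
#' @export
assignROI <- function(labels, overrides = character(0)) {
  roi <- vapply(labels, function(l) {
    u <- toupper(l)
    if (grepl("^(FT|TP|T)[0-9]", u)) return("temporal")
    if (grepl("^FP|^AF|^F[0-9Z]", u)) return("frontal")
    if (grepl("^FC|^C[0-9Z]", u)) return("central")
    if (grepl("^CP|^P[0-9Z]", u)) return("parietal")
    if (grepl("^PO|^O[0-9Z]|^I[Z0-9]", u)) return("occipital")
    "central"
  }, "")
  if (length(overrides)) roi[names(overrides)] <- overrides
  roi
}

#' @rdname assignROI
#' @export
defaultROIMap <- function() assignROI(defaultMontage64())

#' Cross-condition prediction
#'
#' Applies a model trained on the audiovisual condition (restricted to one
#' unimodal feature family) to unimodal stimulus features and unimodal EEG:
#' the generalization test of feature tuning across stimulation conditions.
#'
#' @param modelAV a \linkS4class{TRFModel} trained on AV data with a single
#'   feature family.
#' @param stimUni unimodal feature stream; features must match the model's.
#' @param eegUni unimodal \linkS4class{EEGEpoch} (or time x channels matrix).
#' @param modelTag label for the result.
#' @return an \linkS4class{EvalResult}.
#' @export
crossPredict <- function(modelAV, stimUni, eegUni, modelTag = "cross") {
  if (is(stimUni, "FeatureStream") &&
      !identical(featureNames(stimUni), featureNames(modelAV)))
    stop("feature family mismatch: model expects [",
         paste(featureNames(modelAV), collapse = ", "), "]")
  evaluateTRF(modelAV, stimUni, eegUni, modelTag = modelTag)
}

#' Within- vs cross-condition comparison table and regression
#'
#' Pairs matched within- and cross-condition evaluations per channel (and
#' subject) and regresses r_cross on r_within.
#'
#' @param records data.frame with columns \code{subject}, \code{channel},
#'   \code{roi}, \code{r_within}, \code{r_cross}, \code{model_family} (built
#'   by the caller, e.g. from two \linkS4class{EvalResult}s).
#' @return list with \code{table} (the records) and \code{regression}
#'   (slope, intercept, r per model family).
#' @export
withinVsCrossTable <- function(records) {
  need <- c("subject", "channel", "r_within", "r_cross", "model_family")
  if (!all(need %in% names(records)))
    stop("records must carry columns: ", paste(need, collapse = ", "))
  if (anyNA(records$r_within) || anyNA(records$r_cross))
    stop("unmatched within/cross records (NA correlations)")
  reg <- do.call(rbind, lapply(split(records, records$model_family),
    function(df) {
      fit <- stats::lm(r_cross ~ r_within, data = df)
      data.frame(model_family = df$model_family[1],
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(df$r_within, df$r_cross))
    }))
  rownames(reg) <- NULL
  list(table = records, regression = reg)
}

#' Helper: build a within/cross record table from two evaluations
#'
#' @param within,cross \linkS4class{EvalResult}s over the same channels.
#' @param subject subject id.
#' @param modelFamily family tag (e.g. "auditory", "visual").
#' @param roimap named label -> roi map.
#' @return data.frame suitable for \code{\link{withinVsCrossTable}}.
#' @export
crossPredRecords <- function(within, cross, subject = "S01",
                             modelFamily = "auditory",
                             roimap = defaultROIMap()) {
  stopifnot(identical(channelLabels(within), channelLabels(cross)))
  ch <- channelLabels(within)
  data.frame(subject = subject, channel = ch,
             roi = unname(roimap[ch]),
             r_within = rValues(within), r_cross = rValues(cross),
             model_family = modelFamily, stringsAsFactors = FALSE)
}

#' Per-channel correlation between two models' weights
#'
#' For each channel, the Pearson correlation between the two flattened
#' (features x lags) weight matrices, on the native scale. Symmetric in its
#' arguments.
#'
#' @param m1,m2 \linkS4class{TRFModel}s with identical features and lags.
#' @return named per-channel correlation vector.
#' @export
weightCorrelationMap <- function(m1, m2) {
  if (!identical(m1@featureNames, m2@featureNames))
    stop("models have different feature sets")
  if (!identical(m1@lags, m2@lags))
    stop("models have different delay grids")
  if (!identical(dim(m1@weights), dim(m2@weights)))
    stop("weight shape mismatch")
  w1 <- nativeWeights(m1); w2 <- nativeWeights(m2)
  n <- dim(w1)[3]
  r <- vapply(seq_len(n), function(i)
    stats::cor(as.vector(w1[, , i]), as.vector(w2[, , i])), 0)
  stats::setNames(r, m1@channelLabels)
}

#' Per-channel correlation between two conditions' EEG
#'
#' Pearson correlation of the (band-passed) EEG time courses per channel,
#' between two epochs of the same trailer; both raw correlations and a
#' min-max normalized version (for topography display) are returned.
#'
#' @param e1,e2 \linkS4class{EEGEpoch}s of the same trailer and channel set
#'   (trimmed to the common length).
#' @return data.frame with channel, r (raw) and rNormalized.
#' @export
eegConditionCorrelation <- function(e1, e2) {
  if (!identical(trailerId(e1), trailerId(e2)))
    stop("epochs come from different trailers")
  if (!identical(channelLabels(e1), channelLabels(e2)))
    stop("epochs have different channel sets")
  n <- min(ncol(epochData(e1)), ncol(epochData(e2)))
  r <- colCorr(t(epochData(e1)[, seq_len(n), drop = FALSE]),
               t(epochData(e2)[, seq_len(n), drop = FALSE]))
  rng <- range(r)
  rn <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else rep(0.5, length(r))
  data.frame(channel = channelLabels(e1), r = r, rNormalized = rn,
             stringsAsFactors = FALSE)
}

#' ROI-level summary with paired permutation comparison
#'
#' Aggregates per-channel prediction accuracies into ROI x condition means
#' and SDs, and compares conditions pairwise with a within-subject sign-flip
#' permutation test on subject-mean differences (all channels pooled).
#'
#' @param records data.frame with columns \code{subject}, \code{condition},
#'   \code{channel}, \code{r}, and optionally \code{model_tag}.
#' @param roimap named label -> roi map.
#' @param nPermutations sign-flip permutations (10000).
#' @param seed RNG seed.
#' @return list with \code{summary} (roi x condition table) and
#'   \code{comparisons} (pairwise permutation p-values; requires >= 2
#'   subjects).
#' @export
roiSummary <- function(records, roimap = defaultROIMap(),
                       nPermutations = 10000, seed = 0) {
  need <- c("subject", "condition", "channel", "r")
  if (!all(need %in% names(records)))
    stop("records must carry columns: ", paste(need, collapse = ", "))
  records$roi <- unname(roimap[records$channel])
  if (anyNA(records$roi)) {
    warning("channel(s) without ROI assignment omitted")
    records <- records[!is.na(records$roi), , drop = FALSE]
  }
  smry <- stats::aggregate(r ~ roi + condition, records,
                           function(v) c(mean = mean(v), sd = stats::sd(v),
                                         n = length(v)))
  smry <- do.call(data.frame, smry)
  names(smry) <- c("roi", "condition", "mean_r", "sd_r", "n_channels")
  conds <- unique(records$condition)
  comparisons <- NULL
  if (length(conds) >= 2L) {
    subjMean <- stats::aggregate(r ~ subject + condition, records, mean)
    nSubj <- length(unique(subjMean$subject))
    if (nSubj < 2L)
      stop("paired permutation test needs >= 2 subjects")
    set.seed(seed)
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      a <- subjMean$r[subjMean$condition == pr[1]]
      b <- subjMean$r[subjMean$condition == pr[2]]
      names(a) <- subjMean$subject[subjMean$condition == pr[1]]
      names(b) <- subjMean$subject[subjMean$condition == pr[2]]
      common <- intersect(names(a), names(b))
      d <- a[common] - b[common]
      obs <- abs(mean(d))
      flips <- matrix(sample(c(-1, 1), nPermutations * length(d),
                             replace = TRUE), nPermutations)
      null <- abs(rowMeans(sweep(flips, 2L, d, "*")))
      data.frame(condition1 = pr[1], condition2 = pr[2],
                 meanDiff = mean(d),
                 p = (1 + sum(null >= obs)) / (1 + nPermutations))
    }))
  }
  list(summary = smry, comparisons = comparisons)
}
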