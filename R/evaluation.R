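#' Contiguous cross-validation folds over the time axis
#'
#' Splits 1..T into nFolds contiguous held-out blocks of near-equal size
#' (the first \code{T %% nFolds} blocks get the extra row). Rows within
#' \code{trim} of a held-out block's boundary are excluded from that
#' fold's training rows, guarding against hemodynamic leakage between
#' training and test.
#'
#' @param T number of time points.
#' @param nFolds number of folds (default 10; must be >= 2 so that
#'   training rows exist).
#' @param trim rows excluded from training on each side of the held-out
#'   block (default 0).
#' @return A \linkS4class{FoldPlan}.
#' @export
makeFolds <- function(T, nFolds = 10, trim = 0) {
  T <- as.integer(T)
  nFolds <- as.integer(nFolds)
  trim <- as.integer(trim)
  stopIfNot(nFolds >= 2,
            "nFolds must be >= 2 (a single fold leaves no training rows)")
  stopIfNot(trim >= 0, "trim must be non-negative")
  minT <- nFolds * (1L + 2L * trim)
  if (T < minT)
    stop("T = ", T, " too small for ", nFolds, " folds with trim ", trim,
         "; need at least T = ", minT, call. = FALSE)
  base <- T %/% nFolds
  sizes <- rep(base, nFolds) + as.integer(seq_len(nFolds) <= T %% nFolds)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  heldOut <- training <- vector("list", nFolds)
  for (k in seq_len(nFolds)) {
    heldOut[[k]] <- seq.int(starts[k], ends[k])
    trimmed <- seq.int(max(1L, starts[k] - trim),
                       min(T, ends[k] + trim))
    training[[k]] <- setdiff(seq_len(T), trimmed)
    if (!length(training[[k]]))
      stop("fold ", k, " has no training rows; reduce trim or nFolds",
           call. = FALSE)
  }
  new("FoldPlan", nFolds = nFolds, heldOut = heldOut,
      training = training, trim = trim, T = T)
}

#' Cut held-out blocks into non-overlapping test segments
#'
#' Each held-out block is divided into the maximal number of disjoint
#' left-aligned segments of \code{segLen} TRs; leftover rows at the end
#' of a block are unused.
#'
#' @param fold a \linkS4class{FoldPlan}.
#' @param segLen segment length in TRs (default 20).
#' @return A \linkS4class{SegmentSet}.
#' @export
segmentSeries <- function(fold, segLen = 20) {
  stopIfNot(is(fold, "FoldPlan"), "fold must be a FoldPlan")
  segLen <- as.integer(segLen)
  stopIfNot(segLen >= 1, "segLen must be >= 1")
  out <- list()
  for (k in seq_len(fold@nFolds)) {
    block <- fold@heldOut[[k]]
    nseg <- length(block) %/% segLen
    if (nseg == 0) next
    starts <- block[1] + (seq_len(nseg) - 1L) * segLen
    out[[length(out) + 1L]] <-
      data.frame(fold = k, start = starts, end = starts + segLen - 1L)
  }
  if (!length(out))
    stop("segment length ", segLen,
         " exceeds every held-out block; no segments available",
         call. = FALSE)
  new("SegmentSet", segLen = segLen,
      segments = do.call(rbind, out))
}

#' Score one two-alternative trial
#'
#' The trial is correct (score 1) when the observed group segment is
#' strictly closer in Euclidean distance to the prediction for the true
#' passage than to the prediction for the alternative passage; an exact
#' tie scores 0.5.
#'
#' @param observed,predictedTrue,predictedAlt matrices of identical
#'   shape (TRs x pooled voxels).
#' @return 0, 0.5 or 1.
#' @export
classifyPair <- function(observed, predictedTrue, predictedAlt) {
  stopIfNot(identical(dim(observed), dim(predictedTrue)) &&
              identical(dim(observed), dim(predictedAlt)),
            "observed and predicted segments must have identical shapes")
  dTrue <- sum((observed - predictedTrue)^2)
  dAlt <- sum((observed - predictedAlt)^2)
  if (dTrue < dAlt) 1 else if (dTrue > dAlt) 0 else 0.5
}

#' Concatenate per-subject segments into a group segment
#'
#' Voxel axes are concatenated in the given (recorded) subject order;
#' no values are ever averaged across subjects.
#'
#' @param perSubject list of TRs x voxels matrices, one per subject.
#' @return TRs x (sum of voxels) matrix.
#' @export
groupConcatenate <- function(perSubject) {
  stopIfNot(length(perSubject) >= 1, "need at least one subject")
  rows <- vapply(perSubject, nrow, integer(1))
  if (length(unique(rows)) != 1)
    stop("TR counts differ across subjects: ",
         paste(rows, collapse = ", "), call. = FALSE)
  do.call(cbind, perSubject)
}

#' Cross-validated two-alternative passage classification
#'
#' The end-to-end evaluation: in each fold, per-subject encoding models
#' are trained on 90\% of the run (design and fMRI standardized with
#' training-fold statistics only), the held-out 10\% is cut into 20-TR
#' segments, and each observed group-concatenated segment is compared
#' against the model's predictions for its own passage and for randomly
#' drawn alternative passages from the same fold's held-out pool. The
#' score over all trials is the classification accuracy; chance is 50\%.
#' Distances are computed on the standardized scale used in training.
#'
#' @param subjects a \linkS4class{SubjectData} or list of them (equal TR
#'   counts).
#' @param story an \linkS4class{AnnotatedStory} (resampled internally at
#'   \code{tr}) or a ready \linkS4class{FeatureTimeSeries}.
#' @param featureSet NULL for all features; the name of a feature set
#'   declared by the story; or a character vector of feature names.
#' @param tr sampling period in seconds (used when story is an
#'   AnnotatedStory).
#' @param nLags number of response-signature lags (default 4).
#' @param nFolds number of outer folds (default 10).
#' @param segLen test segment length in TRs (default 20).
#' @param nPairings alternatives drawn per true segment, without
#'   replacement from the same fold's other segments (default 2, the
#'   maximum available under the defaults; capped at what exists).
#' @param trim training-rows trim at block boundaries (default nLags).
#' @param penaltyGrid,innerFolds passed to \code{\link{fitRidge}}.
#' @param seed RNG seed for alternative sampling.
#' @return A \linkS4class{ClassificationResult}.
#' @export
runClassification <- function(subjects, story, featureSet = NULL,
                              tr = 2, nLags = 4, nFolds = 10,
                              segLen = 20, nPairings = 2, trim = nLags,
                              penaltyGrid = 10^(0:7), innerFolds = 5,
                              seed = NULL) {
  if (is(subjects, "SubjectData")) subjects <- list(subjects)
  stopIfNot(length(subjects) >= 1, "need at least one subject")
  Ts <- vapply(subjects, function(s) nrow(s@fmri), integer(1))
  if (length(unique(Ts)) != 1)
    stop("subjects have differing TR counts: ",
         paste(Ts, collapse = ", "), call. = FALSE)
  T <- Ts[1]
  fts <- resolveFeatureSeries(story, featureSet, tr)
  if (nrow(fts@values) != T)
    stop("feature series has ", nrow(fts@values),
         " TRs but the fMRI data has ", T, call. = FALSE)
  stopIfNot(nPairings >= 1, "nPairings must be >= 1")

  X <- buildLaggedDesign(fts, nLags)
  plan <- makeFolds(T, nFolds, trim)
  segs <- segmentSeries(plan, segLen)@segments

  trials <- list()
  withSeed(seed, {
    for (k in seq_len(plan@nFolds)) {
      sk <- segs[segs$fold == k, , drop = FALSE]
      if (nrow(sk) < 2) next        # no alternatives within this fold
      trn <- plan@training[[k]]
      obsList <- predList <- vector("list", length(subjects))
      for (s in seq_along(subjects)) {
        std <- standardizePair(X@values, subjects[[s]]@fmri, trn)
        fit <- fitRidge(std$X[trn, , drop = FALSE],
                        std$Y[trn, , drop = FALSE],
                        penaltyGrid = penaltyGrid,
                        innerFolds = innerFolds, standardize = FALSE)
        obsList[[s]] <- std$Y
        predList[[s]] <- std$X %*% t(weights(fit))
      }
      for (i in seq_len(nrow(sk))) {
        alts <- setdiff(seq_len(nrow(sk)), i)
        nPick <- min(nPairings, length(alts))
        pick <- alts[sample.int(length(alts), nPick)]
        rowsI <- sk$start[i]:sk$end[i]
        obs <- groupConcatenate(lapply(obsList, function(m)
          m[rowsI, , drop = FALSE]))
        predTrue <- groupConcatenate(lapply(predList, function(m)
          m[rowsI, , drop = FALSE]))
        for (j in pick) {
          rowsJ <- sk$start[j]:sk$end[j]
          predAlt <- groupConcatenate(lapply(predList, function(m)
            m[rowsJ, , drop = FALSE]))
          trials[[length(trials) + 1L]] <- data.frame(
            fold = k, segmentStart = sk$start[i],
            alternativeStart = sk$start[j],
            score = classifyPair(obs, predTrue, predAlt))
        }
      }
    }
  })
  if (!length(trials))
    stop("no fold provided two or more segments; nothing to classify ",
         "(need at least 2 segments in some held-out block)",
         call. = FALSE)
  trials <- do.call(rbind, trials)
  new("ClassificationResult",
      nTrials = nrow(trials), nCorrect = sum(trials$score),
      accuracy = sum(trials$score) / nrow(trials),
      trials = trials, seed = if (is.null(seed)) NA_real_ else seed)
}

# Turn (story | fts) x featureSet into the FeatureTimeSeries to model.
resolveFeatureSeries <- function(story, featureSet, tr) {
  fts <- if (is(story, "AnnotatedStory")) resampleToTr(story, tr)
         else if (is(story, "FeatureTimeSeries")) story
         else stop("story must be an AnnotatedStory or FeatureTimeSeries",
                   call. = FALSE)
  if (is.null(featureSet)) return(fts)
  if (is(story, "AnnotatedStory") && length(featureSet) == 1 &&
      featureSet %in% names(featureSets(story)))
    return(selectFeatureSet(fts, featureSet, story))
  idx <- match(featureSet, fts@featureNames)
  if (anyNA(idx))
    stop("unknown feature set or feature names: ",
         paste(featureSet[is.na(idx)], collapse = ", "), call. = FALSE)
  new("FeatureTimeSeries", values = fts@values[, idx, drop = FALSE],
      tr = fts@tr, featureNames = featureSet)
}
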