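#' @import methods
NULL

#' AnnotatedStory: a word-level stimulus description
#'
#' One row per presented word: the token itself, its onset in seconds from
#' run start, and a vector of real-valued feature annotations (indicator
#' columns for discrete properties such as part of speech or character
#' identity, continuous columns for properties such as word length).
#' Named feature sets (e.g. \code{"visual"}, \code{"syntax"},
#' \code{"semantics"}, \code{"discourse"}) group the columns into the
#' feature families that are analysed one at a time in representation
#' mapping.
#'
#' @slot words character vector of presented tokens.
#' @slot onsets numeric, seconds from run start, strictly increasing.
#' @slot features words x F numeric matrix of feature values (no NaN).
#' @slot featureNames character of length F, unique column names.
#' @slot featureSets named list mapping set name to a character vector of
#'   feature names; every member must name an existing column.
#' @slot wordDuration seconds each word is displayed (0.5 s RSVP default).
#' @slot duration declared run length in seconds; must cover every onset.
#'
#' @export
setClass("AnnotatedStory",
  representation(
    words = "character",
    onsets = "numeric",
    features = "matrix",
    featureNames = "character",
    featureSets = "list",
    wordDuration = "numeric",
    duration = "numeric"
  )
)

setValidity("AnnotatedStory", function(object) {
  n <- length(object@words)
  msg <- character()
  if (length(object@onsets) != n)
    msg <- c(msg, "onsets must have one entry per word")
  if (n > 1 && any(diff(object@onsets) <= 0))
    msg <- c(msg, "onsets must be strictly increasing")
  if (any(object@onsets < 0))
    msg <- c(msg, "onsets must be non-negative")
  if (nrow(object@features) != n)
    msg <- c(msg, "features must have one row per word")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite (no NaN/Inf)")
  if (ncol(object@features) != length(object@featureNames))
    msg <- c(msg, "featureNames length must match feature columns")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "featureNames must be unique")
  unknown <- setdiff(unlist(object@featureSets), object@featureNames)
  if (length(unknown))
    msg <- c(msg, paste0("featureSets reference unknown features: ",
                         paste(unknown, collapse = ", ")))
  if (length(object@featureSets) && is.null(names(object@featureSets)))
    msg <- c(msg, "featureSets must be named")
  if (object@wordDuration <= 0)
    msg <- c(msg, "wordDuration must be positive")
  if (n > 0 && object@duration < max(object@onsets))
    msg <- c(msg, "duration must cover the last onset")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedStory
#'
#' @param words character vector of tokens.
#' @param onsets numeric onsets in seconds (strictly increasing).
#' @param features numeric matrix, one row per word.
#' @param featureNames optional column names (defaults to
#'   \code{colnames(features)}).
#' @param featureSets named list of character vectors grouping features.
#' @param wordDuration word presentation time in seconds (default 0.5).
#' @param duration declared run length in seconds; defaults to the last
#'   onset plus one word duration.
#' @return An \linkS4class{AnnotatedStory}.
#' @export
AnnotatedStory <- function(words, onsets, features,
                           featureNames = colnames(features),
                           featureSets = list(),
                           wordDuration = 0.5,
                           duration = NULL) {
  features <- as.matrix(features)
  if (is.null(featureNames))
    featureNames <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- featureNames
  if (is.null(duration))
    duration <- if (length(onsets)) max(onsets) + wordDuration else 0
  new("AnnotatedStory", words = words, onsets = as.numeric(onsets),
      features = features, featureNames = featureNames,
      featureSets = featureSets, wordDuration = wordDuration,
      duration = duration)
}

#' FeatureTimeSeries: TR-aligned story feature magnitudes
#'
#' The per-word annotations collapsed onto the fMRI sampling grid: row t
#' holds the sum of the feature vectors of all words presented during the
#' t-th repetition time (TR), i.e. the feature magnitude x_f(t).
#'
#' @slot values T x F numeric matrix.
#' @slot tr sampling period in seconds (2 s default).
#' @slot featureNames character of length F.
#' @export
setClass("FeatureTimeSeries",
  representation(values = "matrix", tr = "numeric",
                 featureNames = "character")
)

setValidity("FeatureTimeSeries", function(object) {
  msg <- character()
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (ncol(object@values) != length(object@featureNames))
    msg <- c(msg, "featureNames length must match value columns")
  if (length(msg)) msg else TRUE
})

#' DesignMatrix: lagged (finite-impulse-response) design
#'
#' Each feature column of a \linkS4class{FeatureTimeSeries} is expanded into
#' L lagged copies so that a feature occurring at time t can influence the
#' signal at t + 1..L TRs (2..8 s at the defaults), with zero padding at the
#' start of the run. Columns are ordered feature-major, lag-minor.
#'
#' @slot values T x (F*L) numeric matrix.
#' @slot nLags number of lags L (default 4).
#' @slot lagSeconds offsets of the lags in seconds, strictly increasing.
#' @slot columnIndex data.frame(feature, lag, column) mapping (f, d) pairs
#'   to columns of \code{values}.
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", nLags = "integer",
                 lagSeconds = "numeric", columnIndex = "data.frame")
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (nrow(object@columnIndex) != ncol(object@values))
    msg <- c(msg, "columnIndex must have one row per design column")
  if (any(diff(object@lagSeconds) <= 0))
    msg <- c(msg, "lagSeconds must be strictly increasing")
  if (length(object@lagSeconds) != object@nLags)
    msg <- c(msg, "lagSeconds length must equal nLags")
  if (length(msg)) msg else TRUE
})

#' EncodingModel: per-voxel response signatures and penalties
#'
#' The fitted voxelwise linear model. Row v of \code{weights} holds the
#' F*L lagged weights w_{v,f,d} of voxel v -- its learned temporal response
#' signature for every feature -- and \code{penalties[v]} the ridge penalty
#' selected for that voxel by inner cross-validation. Weights live on the
#' standardized scale recorded in \code{standardization}; \code{predict}
#' undoes the transform.
#'
#' @slot weights V x (F*L) numeric matrix.
#' @slot penalties numeric of length V, selected per-voxel ridge penalties.
#' @slot columnIndex as in \linkS4class{DesignMatrix}.
#' @slot lagSeconds lag offsets in seconds.
#' @slot standardization list with X/Y centers and scales (identity when
#'   fitted unstandardized).
#' @export
setClass("EncodingModel",
  representation(weights = "matrix", penalties = "numeric",
                 columnIndex = "data.frame", lagSeconds = "numeric",
                 standardization = "list")
)

setValidity("EncodingModel", function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@penalties))
    msg <- c(msg, "one penalty per voxel required")
  if (any(object@penalties < 0))
    msg <- c(msg, "penalties must be non-negative")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (nrow(object@columnIndex) != ncol(object@weights))
    msg <- c(msg, "columnIndex must match weight columns")
  if (length(msg)) msg else TRUE
})

#' SubjectData: one subject's fMRI run
#'
#' @slot subjectId character identifier.
#' @slot fmri T x V numeric matrix (time by voxel).
#' @slot coords V x 3 numeric matrix of MNI millimetre coordinates.
#' @slot voxelSize voxel edge length in mm.
#' @export
setClass("SubjectData",
  representation(subjectId = "character", fmri = "matrix",
                 coords = "matrix", voxelSize = "numeric")
)

setValidity("SubjectData", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3)
    msg <- c(msg, "coords must be V x 3")
  if (nrow(object@coords) != ncol(object@fmri))
    msg <- c(msg, "one coordinate row per fMRI column required")
  if (anyDuplicated(object@coords) > 0)
    msg <- c(msg, "duplicate voxel coordinates within a subject")
  if (object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectData
#'
#' @param subjectId identifier string.
#' @param fmri T x V matrix.
#' @param coords V x 3 mm coordinates.
#' @param voxelSize voxel edge in mm (default 3).
#' @return A \linkS4class{SubjectData}.
#' @export
SubjectData <- function(subjectId, fmri, coords, voxelSize = 3) {
  new("SubjectData", subjectId = as.character(subjectId),
      fmri = as.matrix(fmri), coords = as.matrix(coords),
      voxelSize = voxelSize)
}

#' FoldPlan: contiguous cross-validation folds over the time axis
#'
#' @slot nFolds number of folds.
#' @slot heldOut list of integer vectors, the held-out rows per fold
#'   (contiguous blocks partitioning 1..T).
#' @slot training list of integer vectors, the training rows per fold
#'   (held-out block and trim rows excluded).
#' @slot trim number of rows excluded from training on each side of a
#'   held-out block (hemodynamic leakage guard).
#' @slot T total number of rows.
#' @export
setClass("FoldPlan",
  representation(nFolds = "integer", heldOut = "list", training = "list",
                 trim = "integer", T = "integer")
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  all_held <- sort(unlist(object@heldOut))
  if (!identical(all_held, seq_len(object@T)))
    msg <- c(msg, "held-out blocks must partition 1..T")
  for (k in seq_len(object@nFolds)) {
    if (length(intersect(object@heldOut[[k]], object@training[[k]])))
      msg <- c(msg, "training and held-out rows must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' SegmentSet: non-overlapping test segments within held-out blocks
#'
#' @slot segLen segment length in TRs.
#' @slot segments data.frame(fold, start, end), rows fully inside one
#'   held-out block, non-overlapping.
#' @export
setClass("SegmentSet",
  representation(segLen = "integer", segments = "data.frame"))

#' ClassificationResult: outcome of two-alternative passage classification
#'
#' @slot nTrials total number of segment-vs-alternative trials.
#' @slot nCorrect summed scores (ties count 0.5).
#' @slot accuracy nCorrect / nTrials.
#' @slot trials data.frame with per-trial breakdown (fold, segment start,
#'   alternative start, score).
#' @slot seed seed used for alternative sampling.
#' @export
setClass("ClassificationResult",
  representation(nTrials = "integer", nCorrect = "numeric",
                 accuracy = "numeric", trials = "data.frame",
                 seed = "numeric")
)

setValidity("ClassificationResult", function(object) {
  if (object@nTrials > 0 &&
      (object@accuracy < 0 || object@accuracy > 1))
    return("accuracy must lie in [0, 1]")
  TRUE
})

#' SearchlightResult: per-location, per-feature-set accuracy map
#'
#' @slot map data.frame with columns x, y, z (centre mm coordinates),
#'   featureSet, nVoxels, nTrials, accuracy, p, q, significant, missing.
#' @slot edgeVoxels cube edge in voxels.
#' @slot voxelSize voxel edge in mm.
#' @slot seed base seed.
#' @export
setClass("SearchlightResult",
  representation(map = "data.frame", edgeVoxels = "integer",
                 voxelSize = "numeric", seed = "numeric")
)

#' NullDistribution: empirical chance-level accuracies
#'
#' @slot accuracies numeric vector of null accuracies in [0, 1].
#' @slot nPermutations number of permutations run.
#' @slot scheme description of the generating scheme.
#' @slot seed seed used.
#' @export
setClass("NullDistribution",
  representation(accuracies = "numeric", nPermutations = "integer",
                 scheme = "character", seed = "numeric")
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (object@nPermutations < 1)
    msg <- c(msg, "nPermutations must be >= 1")
  if (length(object@accuracies) &&
      (min(object@accuracies) < 0 || max(object@accuracies) > 1))
    msg <- c(msg, "null accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative parameters behind a synthetic dataset
#'
#' @slot weights list (one per subject) of V x (F*L) true weight matrices.
#' @slot regions named list; each element has \code{featureSet} and
#'   \code{voxels} (indices into the voxel grid).
#' @slot ar1 AR(1) noise coefficient.
#' @slot snr requested signal-to-noise ratio (SD(signal)/SD(noise) per
#'   driven voxel).
#' @slot noiseSd list of per-subject per-voxel noise SDs actually used.
#' @slot columnIndex column layout of the weight matrices.
#' @export
setClass("GroundTruth",
  representation(weights = "list", regions = "list", ar1 = "numeric",
                 snr = "numeric", noiseSd = "list",
                 columnIndex = "data.frame")
)
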