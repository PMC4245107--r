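#' @include AllClasses.R
NULL

#' Accessors for storyEncoding classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of one of the package classes.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("featureSets", function(object) standardGeneric("featureSets"))

#' @rdname accessors
#' @export
setGeneric("featureSets<-",
           function(object, value) standardGeneric("featureSets<-"))

#' @rdname accessors
#' @export
setGeneric("values", function(object) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("fmriData", function(object) standardGeneric("fmriData"))

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))

#' @rdname accessors
#' @export
setGeneric("penalties", function(object) standardGeneric("penalties"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("resultMap", function(object) standardGeneric("resultMap"))

#' @rdname accessors
#' @export
setGeneric("nullAccuracies",
           function(object) standardGeneric("nullAccuracies"))

setMethod("featureNames", "AnnotatedStory", function(object)
  object@featureNames)
setMethod("featureNames", "FeatureTimeSeries", function(object)
  object@featureNames)
setMethod("featureSets", "AnnotatedStory", function(object)
  object@featureSets)
setMethod("featureSets<-", "AnnotatedStory", function(object, value) {
  object@featureSets <- value
  validObject(object)
  object
})
setMethod("values", "FeatureTimeSeries", function(object) object@values)
setMethod("values", "DesignMatrix", function(object) object@values)
setMethod("trSeconds", "FeatureTimeSeries", function(object) object@tr)
setMethod("fmriData", "SubjectData", function(object) object@fmri)
setMethod("voxelCoords", "SubjectData", function(object) object@coords)
setMethod("penalties", "EncodingModel", function(object) object@penalties)
setMethod("accuracy", "ClassificationResult", function(object)
  object@accuracy)
setMethod("nTrials", "ClassificationResult", function(object)
  object@nTrials)
setMethod("resultMap", "SearchlightResult", function(object) object@map)
setMethod("nullAccuracies", "NullDistribution", function(object)
  object@accuracies)

#' @describeIn accessors per-voxel weight matrix of an EncodingModel on the
#'   standardized scale.
#' @export
setMethod("weights", "EncodingModel", function(object, ...) object@weights)

setMethod("show", "AnnotatedStory", function(object) {
  cat("AnnotatedStory:", length(object@words), "words,",
      ncol(object@features), "features,",
      sprintf("%.1f s", object@duration), "\n")
  if (length(object@featureSets))
    cat("  feature sets:",
        paste(sprintf("%s(%d)", names(object@featureSets),
                      lengths(object@featureSets)), collapse = ", "), "\n")
})

setMethod("show", "FeatureTimeSeries", function(object) {
  cat("FeatureTimeSeries:", nrow(object@values), "TRs x",
      ncol(object@values), "features, TR =", object@tr, "s\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@values), "TRs x",
      ncol(object@values), "columns (",
      length(unique(object@columnIndex$feature)), "features x",
      object@nLags, "lags )\n")
})

setMethod("show", "EncodingModel", function(object) {
  cat("EncodingModel:", nrow(object@weights), "voxels,",
      ncol(object@weights), "lagged weights each\n")
  cat("  penalty range: [", format(min(object@penalties)), ",",
      format(max(object@penalties)), "]\n")
})

setMethod("show", "SubjectData", function(object) {
  cat("SubjectData", object@subjectId, ":", nrow(object@fmri), "TRs x",
      ncol(object@fmri), "voxels,", object@voxelSize, "mm voxels\n")
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: accuracy %.3f over %d trials\n",
              object@accuracy, object@nTrials))
})

setMethod("show", "SearchlightResult", function(object) {
  m <- object@map
  cat("SearchlightResult:", nrow(m), "rows (",
      length(unique(m$featureSet)), "feature sets x",
      nrow(unique(m[, c("x", "y", "z")])), "centres ), cube edge",
      object@edgeVoxels, "voxels\n")
  ok <- !m$missing
  if (any(ok))
    cat(sprintf("  accuracy range: [%.3f, %.3f]\n",
                min(m$accuracy[ok]), max(m$accuracy[ok])))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d accuracies from %d permutations (%s), mean %.3f\n",
    length(object@accuracies), object@nPermutations, object@scheme,
    mean(object@accuracies)))
})
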