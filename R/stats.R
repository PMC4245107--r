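#' Empirical chance-level distribution of classification accuracy
#'
#' Estimates the distribution of accuracies the classification pipeline
#' produces when the stimulus carries no information about the fMRI
#' signal. Each permutation circularly shifts the TR-aligned feature time
#' series by a uniform random offset of at least twice the segment length
#' before training and classification: the shift destroys the stimulus-
#' response alignment while preserving the temporal autocorrelation of
#' both series (which shuffling segment labels would not).
#'
#' @param subjects list of \linkS4class{SubjectData}.
#' @param story \linkS4class{AnnotatedStory} or
#'   \linkS4class{FeatureTimeSeries}.
#' @param featureSet as in \code{\link{runClassification}}.
#' @param nPermutations number of permutations (>= 20 recommended for
#'   usable p-value resolution).
#' @param tr,nLags,nFolds,segLen,nPairings,trim,penaltyGrid,innerFolds
#'   classification configuration.
#' @param seed RNG seed.
#' @return A \linkS4class{NullDistribution} pooling one accuracy per
#'   permutation.
#' @export
empiricalNull <- function(subjects, story, featureSet = NULL,
                          nPermutations = 25, tr = 2, nLags = 4,
                          nFolds = 10, segLen = 20, nPairings = 2,
                          trim = nLags, penaltyGrid = 10^(0:7),
                          innerFolds = 5, seed = 1) {
  stopIfNot(nPermutations >= 1, "nPermutations must be >= 1")
  fts <- resolveFeatureSeries(story, featureSet, tr)
  if (is(story, "AnnotatedStory") && !is.null(featureSet) &&
      length(featureSet) == 1 &&
      featureSet %in% names(featureSets(story)))
    featureSet <- NULL                  # already selected
  T <- nrow(fts@values)
  if (T < 4 * segLen)
    stop("offset space too small: need T >= 4 * segLen (T = ", T,
         ", segLen = ", segLen, ")", call. = FALSE)
  accs <- withSeed(seed, {
    offsets <- sample.int(T - 4 * segLen + 1L, nPermutations,
                          replace = TRUE) + 2L * segLen - 1L
    permSeeds <- sample.int(2147483646L, nPermutations)
    vapply(seq_len(nPermutations), function(i) {
      off <- offsets[i]
      shifted <- new("FeatureTimeSeries",
                     values = fts@values[((seq_len(T) - 1L + off) %% T)
                                         + 1L, , drop = FALSE],
                     tr = fts@tr, featureNames = fts@featureNames)
      accuracy(runClassification(
        subjects, shifted, featureSet = NULL, tr = tr, nLags = nLags,
        nFolds = nFolds, segLen = segLen, nPairings = nPairings,
        trim = trim, penaltyGrid = penaltyGrid,
        innerFolds = innerFolds, seed = permSeeds[i]))
    }, numeric(1))
  })
  new("NullDistribution", accuracies = accs,
      nPermutations = as.integer(nPermutations),
      scheme = "circular feature-series shift (offset >= 2 x segLen)",
      seed = seed)
}

#' Add-one empirical permutation p-value
#'
#' \code{p = (1 + #\{null >= accuracy\}) / (1 + n)}; never exactly zero,
#' ties counted against the observed value.
#'
#' @param accuracy observed accuracy (scalar or vector).
#' @param null a \linkS4class{NullDistribution} or numeric vector of null
#'   accuracies.
#' @return p-value(s) in (0, 1].
#' @export
pValue <- function(accuracy, null) {
  nv <- if (is(null, "NullDistribution")) nullAccuracies(null) else null
  stopIfNot(length(nv) >= 1, "null distribution is empty")
  vapply(accuracy, function(a) (1 + sum(nv >= a)) / (1 + length(nv)),
         numeric(1))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard BH: with m ordered p-values, reject the k smallest where k is
#' the largest i with \code{p(i) <= i * q / m}; q-values are the monotone
#' BH-adjusted p-values (via \code{stats::p.adjust}), and the rejection
#' set equals \code{qvalues <= q}.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @param q target false discovery rate in (0, 1), default 0.05.
#' @return list(qvalues, reject) with \code{reject} a logical mask.
#' @export
fdrBH <- function(pvalues, q = 0.05) {
  stopIfNot(length(pvalues) >= 1, "empty p-value vector")
  stopIfNot(all(pvalues > 0 & pvalues <= 1),
            "p-values must lie in (0, 1]")
  stopIfNot(q > 0 && q < 1, "q must lie in (0, 1)")
  qvalues <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = qvalues, reject = qvalues <= q)
}

#' Attach permutation p-values and FDR q-values to a searchlight map
#'
#' Non-missing centres get an add-one permutation p-value against the
#' supplied empirical null (a single pooled null, or a named list with
#' one null per feature set) and BH q-values computed jointly across all
#' non-missing map rows; \code{significant} flags \code{q <= level}.
#'
#' @param result a \linkS4class{SearchlightResult}.
#' @param null a \linkS4class{NullDistribution} or named list of them
#'   keyed by feature set.
#' @param level FDR level (default 0.05).
#' @return The result with p, q and significant columns filled.
#' @export
searchlightSignificance <- function(result, null, level = 0.05) {
  stopIfNot(is(result, "SearchlightResult"),
            "result must be a SearchlightResult")
  m <- result@map
  ok <- !m$missing
  stopIfNot(any(ok), "map has no evaluated centres")
  if (is(null, "NullDistribution")) {
    m$p[ok] <- pValue(m$accuracy[ok], null)
  } else {
    stopIfNot(is.list(null) && !is.null(names(null)),
              "null must be a NullDistribution or a named list of them")
    for (nm in unique(m$featureSet[ok])) {
      if (!nm %in% names(null))
        stop("no null distribution for feature set '", nm, "'",
             call. = FALSE)
      sel <- ok & m$featureSet == nm
      m$p[sel] <- pValue(m$accuracy[sel], null[[nm]])
    }
  }
  bh <- fdrBH(m$p[ok], q = level)
  m$q[ok] <- bh$qvalues
  m$significant[ok] <- bh$reject
  initialize(result, map = m)
}

#' Top-K most accurate centres per feature set
#'
#' The alternative, threshold-free rendering of the representation map:
#' instead of a significance mask, flag the K highest-accuracy centres of
#' each feature set (K defaults to 1000).
#'
#' @param result a \linkS4class{SearchlightResult}.
#' @param k number of centres to flag per feature set.
#' @return The map data.frame with a logical \code{top} column.
#' @export
topAccuracyVoxels <- function(result, k = 1000) {
  stopIfNot(is(result, "SearchlightResult"),
            "result must be a SearchlightResult")
  m <- resultMap(result)
  m$top <- FALSE
  for (nm in unique(m$featureSet)) {
    sel <- which(m$featureSet == nm & !m$missing)
    if (!length(sel)) next
    ord <- sel[order(m$accuracy[sel], decreasing = TRUE)]
    m$top[utils::head(ord, k)] <- TRUE
  }
  m
}
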