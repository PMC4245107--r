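#' Generate a synthetic annotated story
#'
#' Emulates the statistics of a word-level annotated stimulus: words
#' presented at a fixed rate (rapid serial visual presentation, one word
#' per \code{wordPeriod} seconds), a continuous positive right-skewed
#' "visual" column (the letter count of the generated token, plus further
#' log-normal continuous columns when requested), and sparse 0/1
#' indicator columns (discrete annotations such as part of speech or
#' character mentions, active with probability \code{sparsity}). Columns
#' are partitioned into named feature sets: the continuous columns form
#' "visual" and the indicators are dealt round-robin to "syntax",
#' "semantics" and "discourse".
#'
#' @param nWords number of words (>= 1).
#' @param nFeatures total feature columns (>= 2, so that at least two
#'   sets exist).
#' @param sparsity activation probability of indicator columns, in
#'   (0, 1].
#' @param wordPeriod presentation period in seconds (default 0.5).
#' @param seed RNG seed.
#' @return An \linkS4class{AnnotatedStory} with onsets at multiples of
#'   \code{wordPeriod}.
#' @export
generateStory <- function(nWords = 2400, nFeatures = 10, sparsity = 0.1,
                          wordPeriod = 0.5, seed = NULL) {
  stopIfNot(nWords >= 1, "nWords must be >= 1")
  stopIfNot(nFeatures >= 2,
            "nFeatures must be >= 2 (at least two feature sets needed)")
  stopIfNot(sparsity > 0 && sparsity <= 1, "sparsity must be in (0, 1]")
  withSeed(seed, {
    lens <- 1L + stats::rpois(nWords, 4)
    words <- vapply(lens, function(l)
      paste(sample(letters, l, replace = TRUE), collapse = ""),
      character(1))
    nCont <- max(1L, round(nFeatures / 5))
    nInd <- nFeatures - nCont
    cont <- cbind(wordLength = annotateWordLength(words))
    if (nCont > 1)
      cont <- cbind(cont, matrix(
        stats::rlnorm(nWords * (nCont - 1), 0, 0.5), nWords,
        dimnames = list(NULL, paste0("cont", seq_len(nCont - 1)))))
    indSets <- c("syntax", "semantics", "discourse")
    feats <- cont
    setMap <- list(visual = colnames(cont))
    if (nInd > 0) {
      used <- indSets[((seq_len(nInd) - 1L) %% length(indSets)) + 1L]
      indNames <- paste0(used, ".", stats::ave(seq_len(nInd), used,
                                               FUN = seq_along))
      ind <- matrix(stats::rbinom(nWords * nInd, 1, sparsity), nWords,
                    dimnames = list(NULL, indNames))
      feats <- cbind(feats, ind)
      for (s in unique(used))
        setMap[[s]] <- indNames[used == s]
    }
    AnnotatedStory(words = words,
                   onsets = (seq_len(nWords) - 1) * wordPeriod,
                   features = feats, featureSets = setMap,
                   wordDuration = wordPeriod,
                   duration = nWords * wordPeriod)
  })
}

#' Canonical double-gamma HRF sampled at the model's lags
#'
#' The ground-truth temporal response used by the simulator: the standard
#' double-gamma hemodynamic response function (peak ~5 s, undershoot
#' ~15 s, undershoot ratio 1/6) evaluated at the lag offsets and
#' peak-normalized to 1. The estimator never assumes this shape -- it is
#' simulation ground truth only.
#'
#' @param lagSeconds positive, strictly increasing lag offsets (default
#'   c(2, 4, 6, 8)).
#' @return Numeric vector of the same length, maximum 1.
#' @export
hrfSignature <- function(lagSeconds = c(2, 4, 6, 8)) {
  stopIfNot(all(lagSeconds > 0) && all(diff(lagSeconds) > 0),
            "lagSeconds must be positive and strictly increasing")
  h <- stats::dgamma(lagSeconds, shape = 6, rate = 1) -
    stats::dgamma(lagSeconds, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Default region layout: one disjoint region per feature set
#'
#' Assigns each feature set a contiguous region of the voxel grid (slabs
#' along the x axis, restricted in y and z so that a substantial fraction
#' of the grid stays undriven pure-noise tissue). When the grid's x
#' extent is smaller than the number of sets, regions are contiguous runs
#' of voxel indices instead.
#'
#' @param gridDim integer length-3 voxel grid dimensions.
#' @param setNames names of the feature sets to plant.
#' @return Named list of regions, each with \code{featureSet} and
#'   \code{voxels} (linear indices into the grid).
#' @export
defaultLayout <- function(gridDim, setNames) {
  stopIfNot(length(gridDim) == 3 && all(gridDim >= 1),
            "gridDim must be three positive integers")
  n <- length(setNames)
  out <- list()
  if (gridDim[1] >= n) {
    width <- gridDim[1] %/% n
    yMax <- max(1L, ceiling(0.6 * gridDim[2]))
    zMax <- max(1L, ceiling(0.6 * gridDim[3]))
    for (i in seq_len(n)) {
      xs <- ((i - 1L) * width + 1L):(i * width)
      g <- expand.grid(x = xs, y = seq_len(yMax), z = seq_len(zMax))
      vox <- g$x + (g$y - 1L) * gridDim[1] +
        (g$z - 1L) * gridDim[1] * gridDim[2]
      out[[paste0("region.", setNames[i])]] <-
        list(featureSet = setNames[i], voxels = as.integer(vox))
    }
  } else {
    V <- prod(gridDim)
    blk <- max(1L, floor(0.6 * V / n))
    stopIfNot(n * blk <= V, "grid too small for the number of sets")
    for (i in seq_len(n)) {
      vox <- ((i - 1L) * blk + 1L):(i * blk)
      out[[paste0("region.", setNames[i])]] <-
        list(featureSet = setNames[i], voxels = as.integer(vox))
    }
  }
  out
}

#' Generate multi-subject synthetic fMRI from the encoding model
#'
#' Simulates observed fMRI directly from the model's own generative
#' equation: driven voxels receive the lagged feature series multiplied
#' by ground-truth response signatures (random per-voxel amplitudes times
#' the double-gamma shape of \code{\link{hrfSignature}}); noise is AR(1)
#' (fMRI noise is temporally autocorrelated), scaled per driven voxel so
#' that SD(signal)/SD(noise) equals the requested SNR; undriven voxels
#' are pure noise. Each subject's voxel grid is translated by a random
#' offset of at most \code{jitterMm} per axis, emulating small anatomical
#' variations between normalized brains. \code{snr = 0} yields pure noise
#' (no signal at all); \code{snr = Inf} yields noise-free data.
#'
#' @param story an \linkS4class{AnnotatedStory} (typically from
#'   \code{\link{generateStory}}).
#' @param layout region specification as from \code{\link{defaultLayout}}
#'   (default: one slab per feature set the story declares).
#' @param nSubjects number of subjects (default 2).
#' @param snr signal-to-noise ratio per driven voxel (default 1).
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @param jitterMm per-subject whole-grid translation bound in mm
#'   (default 2).
#' @param T number of TRs to keep (default: full story length; must be
#'   >= 100 and no longer than the story allows).
#' @param tr sampling period in seconds (default 2).
#' @param nLags ground-truth signature length (default 4).
#' @param gridDim voxel grid dimensions (default c(8, 5, 5), 200 voxels).
#' @param voxelSize voxel edge in mm (default 3).
#' @param seed RNG seed.
#' @return list(subjects = list of \linkS4class{SubjectData},
#'   truth = \linkS4class{GroundTruth}).
#' @export
generateSubjects <- function(story, layout = NULL, nSubjects = 2,
                             snr = 1, ar1 = 0.3, jitterMm = 2, T = NULL,
                             tr = 2, nLags = 4, gridDim = c(8, 5, 5),
                             voxelSize = 3, seed = NULL) {
  stopIfNot(nSubjects >= 1, "nSubjects must be >= 1")
  stopIfNot(snr >= 0, "snr must be non-negative")
  fts <- resampleToTr(story, tr)
  Tfull <- nrow(fts@values)
  if (is.null(T)) T <- Tfull
  stopIfNot(T >= 100, "T must be >= 100")
  if (T > Tfull)
    stop("requested T = ", T, " exceeds the story's ", Tfull, " TRs",
         call. = FALSE)
  if (is.null(layout))
    layout <- defaultLayout(gridDim, names(featureSets(story)))
  for (rg in layout)
    if (!rg$featureSet %in% names(featureSets(story)))
      stop("layout references unknown feature set '", rg$featureSet,
           "'", call. = FALSE)
  V <- prod(gridDim)
  X <- buildLaggedDesign(fts, nLags)
  Xv <- X@values[seq_len(T), , drop = FALSE]
  h <- hrfSignature(X@lagSeconds)
  ci <- X@columnIndex
  gridIdx <- as.matrix(expand.grid(x = seq_len(gridDim[1]),
                                   y = seq_len(gridDim[2]),
                                   z = seq_len(gridDim[3])))
  sets <- featureSets(story)

  withSeed(seed, {
    subjects <- vector("list", nSubjects)
    truthW <- truthSd <- vector("list", nSubjects)
    for (s in seq_len(nSubjects)) {
      W <- matrix(0, V, ncol(Xv))
      for (rg in layout) {
        featNames <- sets[[rg$featureSet]]
        for (f in featNames) {
          cols <- ci$column[ci$feature == f][order(ci$lag[ci$feature == f])]
          amps <- stats::rnorm(length(rg$voxels), 1, 0.3)
          W[rg$voxels, cols] <- W[rg$voxels, cols] + outer(amps, h)
        }
      }
      signal <- Xv %*% t(W)
      driven <- rowSums(abs(W)) > 0
      innov <- matrix(stats::rnorm(T * V), T, V)
      noise <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, ar1, method = "recursive")))
      sdSig <- apply(signal, 2, stats::sd)
      sdNoise <- apply(noise, 2, stats::sd)
      if (snr == 0) {
        targetSd <- rep(1, V)
        observed <- sweep(noise, 2, targetSd / sdNoise, "*")
      } else if (is.infinite(snr)) {
        targetSd <- rep(0, V)
        observed <- signal
      } else {
        targetSd <- rep(NA_real_, V)
        targetSd[driven] <- sdSig[driven] / snr
        targetSd[!driven] <- if (any(driven))
          stats::median(targetSd[driven]) else 1
        observed <- signal + sweep(noise, 2, targetSd / sdNoise, "*")
      }
      shift <- if (jitterMm > 0) stats::runif(3, -jitterMm, jitterMm)
               else c(0, 0, 0)
      coords <- sweep(gridIdx * voxelSize, 2, shift, "+")
      subjects[[s]] <- SubjectData(
        subjectId = sprintf("sub%02d", s), fmri = observed,
        coords = coords, voxelSize = voxelSize)
      truthW[[s]] <- W
      truthSd[[s]] <- targetSd
    }
    list(subjects = subjects,
         truth = new("GroundTruth", weights = truthW, regions = layout,
                     ar1 = ar1, snr = snr, noiseSd = truthSd,
                     columnIndex = ci))
  })
}
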