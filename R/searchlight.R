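#' Voxels of every subject falling inside a cube
#'
#' The concatenated searchlight pools voxels from all subjects whose MNI
#' coordinates fall into a cube around a centre, each subject keeping its
#' own voxels (no cross-subject averaging); subjects may contribute
#' different numbers of voxels, or none at all.
#'
#' @param centre length-3 mm coordinate of the cube centre.
#' @param subjects list of \linkS4class{SubjectData}.
#' @param edgeVoxels cube edge in voxels, odd (default 5).
#' @return List (one per subject) of integer voxel indices; empty vectors
#'   allowed.
#' @export
cubeNeighborhood <- function(centre, subjects, edgeVoxels = 5) {
  if (is(subjects, "SubjectData")) subjects <- list(subjects)
  stopIfNot(edgeVoxels >= 1 && edgeVoxels %% 2 == 1,
            "edgeVoxels must be odd and >= 1")
  lapply(subjects, function(s) {
    half <- edgeVoxels * s@voxelSize / 2
    d <- abs(sweep(s@coords, 2, centre))
    which(d[, 1] <= half & d[, 2] <= half & d[, 3] <= half)
  })
}

# Restrict a SubjectData to a voxel subset.
subsetVoxels <- function(subject, idx) {
  new("SubjectData", subjectId = subject@subjectId,
      fmri = subject@fmri[, idx, drop = FALSE],
      coords = subject@coords[idx, , drop = FALSE],
      voxelSize = subject@voxelSize)
}

# Default centre grid: every voxel-grid position present in the union of
# the subjects' (rounded) coordinates, optionally strided.
searchlightGrid <- function(subjects, stride = 1) {
  voxelSize <- subjects[[1]]@voxelSize
  idx <- unique(do.call(rbind, lapply(subjects, function(s)
    round(s@coords / voxelSize))))
  if (stride > 1) {
    lo <- apply(idx, 2, min)
    keep <- (idx[, 1] - lo[1]) %% stride == 0 &
      (idx[, 2] - lo[2]) %% stride == 0 &
      (idx[, 3] - lo[3]) %% stride == 0
    idx <- idx[keep, , drop = FALSE]
  }
  idx * voxelSize
}

#' Concatenated searchlight accuracy map
#'
#' Runs the full cross-validated two-alternative classification once per
#' grid centre and feature set, restricted to the voxels of all subjects
#' inside the cube around the centre. Centres pooling fewer than
#' \code{minVoxels} voxels are reported as missing. Per-centre seeds are
#' derived from the centre coordinates, so the map does not depend on
#' grid enumeration order.
#'
#' @param subjects list of \linkS4class{SubjectData}.
#' @param story an \linkS4class{AnnotatedStory} declaring the feature
#'   sets.
#' @param setNames feature sets to map (default: all sets the story
#'   declares).
#' @param grid matrix of centre mm coordinates (default: every voxel
#'   position in the union of the subjects' masks, strided).
#' @param edgeVoxels cube edge in voxels, odd (default 5, i.e. 15 mm at
#'   3 mm voxels).
#' @param stride grid stride in voxels for the default grid (default 1).
#' @param minVoxels minimum pooled voxels for a centre to be evaluated
#'   (default 10).
#' @param tr,nLags,nFolds,segLen,nPairings,trim,penaltyGrid,innerFolds
#'   classification configuration, see \code{\link{runClassification}}.
#' @param seed base seed.
#' @return A \linkS4class{SearchlightResult}; p, q and significance
#'   columns are NA until filled by \code{\link{searchlightSignificance}}.
#' @export
searchlightMap <- function(subjects, story, setNames = NULL, grid = NULL,
                           edgeVoxels = 5, stride = 1, minVoxels = 10,
                           tr = 2, nLags = 4, nFolds = 10, segLen = 20,
                           nPairings = 2, trim = nLags,
                           penaltyGrid = 10^(0:7), innerFolds = 5,
                           seed = 1) {
  if (is(subjects, "SubjectData")) subjects <- list(subjects)
  if (is.null(setNames)) setNames <- names(featureSets(story))
  stopIfNot(length(setNames) >= 1, "no feature sets to map")
  unknown <- setdiff(setNames, names(featureSets(story)))
  if (length(unknown))
    stop("unknown feature set(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(grid)) grid <- searchlightGrid(subjects, stride)
  grid <- as.matrix(grid)
  stopIfNot(nrow(grid) >= 1 && ncol(grid) == 3,
            "grid must be a non-empty matrix of mm coordinates")
  voxelSize <- subjects[[1]]@voxelSize
  ftsAll <- resampleToTr(story, tr)
  ftsBySet <- lapply(setNames, function(nm)
    selectFeatureSet(ftsAll, nm, story))
  names(ftsBySet) <- setNames

  rows <- vector("list", nrow(grid) * length(setNames))
  r <- 0L
  for (c_i in seq_len(nrow(grid))) {
    centre <- grid[c_i, ]
    nb <- cubeNeighborhood(centre, subjects, edgeVoxels)
    pooled <- sum(lengths(nb))
    for (nm in setNames) {
      r <- r + 1L
      if (pooled < minVoxels) {
        rows[[r]] <- data.frame(
          x = centre[1], y = centre[2], z = centre[3], featureSet = nm,
          nVoxels = pooled, nTrials = 0L, accuracy = NA_real_,
          p = NA_real_, q = NA_real_, significant = NA, missing = TRUE)
        next
      }
      subs <- Map(subsetVoxels,
                  subjects[lengths(nb) > 0], nb[lengths(nb) > 0])
      res <- runClassification(
        subs, ftsBySet[[nm]], featureSet = NULL, tr = tr, nLags = nLags,
        nFolds = nFolds, segLen = segLen, nPairings = nPairings,
        trim = trim, penaltyGrid = penaltyGrid, innerFolds = innerFolds,
        seed = centreSeed(seed, centre, voxelSize))
      rows[[r]] <- data.frame(
        x = centre[1], y = centre[2], z = centre[3], featureSet = nm,
        nVoxels = pooled, nTrials = nTrials(res),
        accuracy = accuracy(res), p = NA_real_, q = NA_real_,
        significant = NA, missing = FALSE)
    }
  }
  new("SearchlightResult", map = do.call(rbind, rows),
      edgeVoxels = as.integer(edgeVoxels), voxelSize = voxelSize,
      seed = seed)
}

#' Per-volume 3D Gaussian spatial smoothing of one subject
#'
#' Each fMRI volume of the subject is smoothed independently with an
#' isotropic Gaussian kernel of the given full width at half maximum.
#' Smoothing is strictly within-subject -- it is never applied across
#' subjects, and it is not part of the default pipeline; it is a
#' sensitivity knob for examining how region boundaries in the maps move
#' when the per-voxel penalty selection is disturbed. \code{fwhm = 0}
#' returns the input unchanged.
#'
#' @param subject a \linkS4class{SubjectData}.
#' @param fwhm kernel full width at half maximum in mm (>= 0).
#' @return A smoothed \linkS4class{SubjectData} with the same voxels.
#' @export
smoothVolumes <- function(subject, fwhm) {
  stopIfNot(is(subject, "SubjectData"), "subject must be a SubjectData")
  stopIfNot(is.numeric(fwhm) && length(fwhm) == 1 && fwhm >= 0,
            "fwhm must be a non-negative scalar")
  if (fwhm == 0) return(subject)
  vs <- subject@voxelSize
  sdVox <- fwhm / (2 * sqrt(2 * log(2))) / vs
  lo <- apply(subject@coords, 2, min)
  idx <- round(sweep(subject@coords, 2, lo) / vs) + 1L
  dims <- apply(idx, 2, max)
  lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] +
    (idx[, 3] - 1L) * dims[1] * dims[2]
  radius <- max(1L, ceiling(4 * sdVox))
  kern <- stats::dnorm(-radius:radius, sd = sdVox)
  kern <- kern / sum(kern)
  Ks <- lapply(dims, function(n) {
    outer(seq_len(n), seq_len(n), function(i, j) {
      o <- abs(i - j)
      ifelse(o <= radius, kern[o + radius + 1L], 0)
    })
  })
  out <- subject@fmri
  for (t in seq_len(nrow(out))) {
    A <- array(0, dims)
    A[lin] <- out[t, ]
    A <- smooth3dApply(A, Ks)
    out[t, ] <- A[lin]
  }
  new("SubjectData", subjectId = subject@subjectId, fmri = out,
      coords = subject@coords, voxelSize = vs)
}

# Separable 3D convolution via per-axis banded kernel matrices.
smooth3dApply <- function(A, Ks) {
  d <- dim(A)
  A <- array(Ks[[1]] %*% matrix(A, d[1], d[2] * d[3]), d)
  A <- aperm(A, c(2, 1, 3))
  A <- array(Ks[[2]] %*% matrix(A, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  A <- aperm(A, c(2, 1, 3))
  m <- matrix(aperm(A, c(3, 1, 2)), d[3], d[1] * d[2])
  m <- Ks[[3]] %*% m
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}
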