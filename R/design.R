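#' Build the lagged (finite-impulse-response) design matrix
#'
#' The hemodynamic response delays and smears neural activity over roughly
#' 8 s, so the signal at TR t is modelled as a linear combination of every
#' feature's magnitude at the L preceding TRs (lags 1..L, i.e. 2..8 s at
#' TR = 2 s and L = 4). Column (f, d) at row t equals \code{x_f(t - d)},
#' zero-padded where \code{t - d < 1}. No lag-0 column: the response is
#' assumed not to precede or coincide with acquisition of the triggering
#' word's TR.
#'
#' @param fts a \linkS4class{FeatureTimeSeries}.
#' @param nLags number of lags L (default 4).
#' @return A \linkS4class{DesignMatrix} with F*L columns, feature-major,
#'   lag-minor.
#' @export
buildLaggedDesign <- function(fts, nLags = 4) {
  stopIfNot(is(fts, "FeatureTimeSeries"),
            "fts must be a FeatureTimeSeries")
  stopIfNot(nLags >= 1, "nLags must be >= 1")
  nT <- nrow(fts@values)
  stopIfNot(nLags < nT, "nLags must be smaller than the series length")
  L <- as.integer(nLags)
  F <- ncol(fts@values)
  X <- matrix(0, nT, F * L)
  ci <- data.frame(feature = rep(fts@featureNames, each = L),
                   lag = rep.int(seq_len(L), F),
                   column = seq_len(F * L),
                   stringsAsFactors = FALSE)
  for (f in seq_len(F)) {
    for (d in seq_len(L)) {
      col <- (f - 1L) * L + d
      X[(d + 1L):nT, col] <- fts@values[seq_len(nT - d), f]
    }
  }
  colnames(X) <- paste0(ci$feature, ".lag", ci$lag)
  new("DesignMatrix", values = X, nLags = L,
      lagSeconds = seq_len(L) * fts@tr, columnIndex = ci)
}

#' Column-wise standardization with recorded statistics
#'
#' Computes per-column means and standard deviations on a declared subset
#' of rows (the training rows of a cross-validation fold) so that exactly
#' the same transform can be applied to held-out rows without leakage.
#' Constant columns get scale 1 and are thus mapped to all zeros.
#'
#' @param M numeric matrix (design columns or voxel time series).
#' @param statsFrom integer vector of rows to compute statistics from
#'   (default: all rows).
#' @return A list with \code{center}, \code{scale} (both length ncol(M));
#'   scale is the population (1/n) standard deviation.
#' @export
fitStandardization <- function(M, statsFrom = seq_len(nrow(M))) {
  stopIfNot(length(statsFrom) > 0, "statsFrom must be non-empty")
  sub <- M[statsFrom, , drop = FALSE]
  center <- colMeans(sub)
  scale <- sqrt(colMeans(sweep(sub, 2, center)^2))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' @rdname fitStandardization
#' @param record a record returned by \code{fitStandardization}.
#' @param invert if TRUE, undo the transform instead of applying it.
#' @return \code{applyStandardization}: the transformed matrix.
#' @export
applyStandardization <- function(M, record, invert = FALSE) {
  stopIfNot(ncol(M) == length(record$center),
            "record does not match the matrix columns")
  if (invert)
    sweep(sweep(M, 2, record$scale, "*"), 2, record$center, "+")
  else
    sweep(sweep(M, 2, record$center, "-"), 2, record$scale, "/")
}

# Identity record (used for models fitted on raw inputs).
identityStandardization <- function(p) {
  list(center = rep(0, p), scale = rep(1, p))
}

#' Standardize a design matrix and fMRI matrix together
#'
#' Convenience wrapper: fits per-column statistics on \code{statsFrom}
#' rows of both matrices and returns the transformed pair plus the
#' records needed to transform further rows or undo the transform.
#'
#' @param X a \linkS4class{DesignMatrix} or numeric matrix.
#' @param Y T x V fMRI matrix.
#' @param statsFrom rows to estimate statistics from.
#' @return list(X, Y, recordX, recordY); X is returned in the same class
#'   it came in.
#' @export
standardizePair <- function(X, Y, statsFrom = seq_len(nrow(Y))) {
  isDM <- is(X, "DesignMatrix")
  Xm <- if (isDM) X@values else X
  stopIfNot(nrow(Xm) == nrow(Y), "X and Y must have the same row count")
  recX <- fitStandardization(Xm, statsFrom)
  recY <- fitStandardization(Y, statsFrom)
  Xs <- applyStandardization(Xm, recX)
  if (isDM) {
    X@values <- Xs
    Xs <- X
  }
  list(X = Xs, Y = applyStandardization(Y, recY),
       recordX = recX, recordY = recY)
}
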