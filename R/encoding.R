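#' Fit per-voxel ridge regression with per-voxel penalty selection
#'
#' Fits the voxelwise encoding model: each voxel's time series is a
#' penalized linear combination of the lagged feature columns, i.e. a
#' nonparametric L-point temporal response signature per feature with no
#' assumed hemodynamic shape. A separate ridge penalty is selected for
#' every voxel by inner cross-validation over contiguous time blocks
#' (contiguous, to respect the autocorrelation of fMRI noise): the
#' largest penalty whose mean held-out squared error lies within one
#' standard error (over inner folds) of the minimum wins (the
#' one-standard-error rule; exact ties likewise resolve to the larger
#' penalty). Noise voxels, whose cross-validation curve is flat at large
#' penalties, are thereby assigned very large penalties and effectively
#' silenced -- an automatic voxel selection.
#'
#' The solver eigendecomposes the cross-product of the design once per
#' training fold and reuses it for every voxel and every penalty; the
#' result is the exact penalized least-squares solution
#' \code{(X'X + lambda I)^{-1} X'y}. A zero penalty is solved as the
#' minimum-norm least-squares solution (pseudoinverse), so features that
#' never occur in training get exactly zero weights.
#'
#' @param X a \linkS4class{DesignMatrix} or T x P numeric matrix.
#' @param Y T x V numeric matrix (or vector for a single voxel).
#' @param penaltyGrid positive (or zero) penalties to search; default
#'   decade steps 10^0..10^7. A single value skips the inner search.
#' @param innerFolds number of contiguous inner cross-validation blocks
#'   (default 5).
#' @param seed retained for interface symmetry; the fit is deterministic.
#' @param standardize if TRUE (default), columns of X and Y are centred
#'   and scaled using all supplied rows and the transform is recorded in
#'   the model so that \code{predict} returns values on the original
#'   scale. Set FALSE to fit on the raw inputs.
#' @return An \linkS4class{EncodingModel}.
#' @examples
#' X <- matrix(c(1, 2), 2, 1)
#' y <- c(2, 4)
#' m <- fitRidge(X, y, penaltyGrid = 0, standardize = FALSE)
#' weights(m)          # exactly 2
#' @export
fitRidge <- function(X, Y, penaltyGrid = 10^(0:7), innerFolds = 5,
                     seed = NULL, standardize = TRUE) {
  ci <- NULL
  lagSeconds <- numeric()
  if (is(X, "DesignMatrix")) {
    ci <- X@columnIndex
    lagSeconds <- X@lagSeconds
    X <- X@values
  }
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopIfNot(nrow(X) == nrow(Y), "X and Y must have the same row count")
  stopIfNot(!anyNA(X) && !anyNA(Y), "NaN/NA in inputs")
  stopIfNot(all(is.finite(penaltyGrid)) && length(penaltyGrid) >= 1 &&
              all(penaltyGrid >= 0), "penaltyGrid must be non-negative")
  grid <- sort(unique(as.numeric(penaltyGrid)))
  P <- ncol(X)
  V <- ncol(Y)
  if (is.null(ci))
    ci <- data.frame(feature = colnames(X) %||% paste0("c", seq_len(P)),
                     lag = 1L, column = seq_len(P),
                     stringsAsFactors = FALSE)

  if (standardize) {
    recX <- fitStandardization(X)
    recY <- fitStandardization(Y)
    X <- applyStandardization(X, recX)
    Y <- applyStandardization(Y, recY)
  } else {
    recX <- identityStandardization(P)
    recY <- identityStandardization(V)
  }

  if (length(grid) > 1) {
    stopIfNot(nrow(X) >= innerFolds && innerFolds >= 2,
              "need at least innerFolds rows and innerFolds >= 2")
    G <- length(grid)
    foldMSE <- array(0, c(V, G, innerFolds))
    plan <- makeFolds(nrow(X), innerFolds, trim = 0)
    for (k in seq_len(innerFolds)) {
      trn <- plan@training[[k]]
      tst <- plan@heldOut[[k]]
      sol <- ridgeSolver(X[trn, , drop = FALSE], Y[trn, , drop = FALSE])
      for (g in seq_len(G)) {
        W <- sol(grid[g])                       # P x V
        R <- Y[tst, , drop = FALSE] - X[tst, , drop = FALSE] %*% W
        foldMSE[, g, k] <- colSums(R^2) / length(tst)
      }
    }
    # one-standard-error rule, shrinking on ties and near-ties: take the
    # largest penalty whose mean CV error is within one SE (over inner
    # folds) of the minimum -- noise voxels, whose CV curve is flat for
    # large penalties, are thereby pushed to the top of the grid
    mseMean <- apply(foldMSE, c(1, 2), mean)
    mseSE <- apply(foldMSE, c(1, 2), stats::sd) / sqrt(innerFolds)
    idxMin <- max.col(-mseMean, ties.method = "last")
    thr <- mseMean[cbind(seq_len(V), idxMin)] +
      mseSE[cbind(seq_len(V), idxMin)]
    ok <- mseMean <= thr
    best <- G + 1L - max.col(ok[, G:1, drop = FALSE],
                             ties.method = "first")
  } else {
    best <- rep(1L, V)
  }
  lambda <- grid[best]

  sol <- ridgeSolver(X, Y)
  Wt <- matrix(0, V, P)
  for (lam in unique(lambda)) {
    vox <- which(lambda == lam)
    Wt[vox, ] <- t(sol(lam, vox))
  }
  colnames(Wt) <- colnames(X)
  new("EncodingModel", weights = Wt, penalties = lambda,
      columnIndex = ci, lagSeconds = as.numeric(lagSeconds),
      standardization = list(X = recX, Y = recY))
}

# Closure solving (X'X + lambda I) W = X'Y for any lambda from a single
# eigendecomposition; lambda = 0 falls back to the minimum-norm solution.
ridgeSolver <- function(X, Y) {
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  eig <- eigen(XtX, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  Q <- eig$vectors
  tol <- max(ev, 0) * 1e-12
  function(lambda, voxels = NULL) {
    rhs <- if (is.null(voxels)) XtY else XtY[, voxels, drop = FALSE]
    d <- if (lambda == 0) ifelse(ev > tol, 1 / ev, 0) else 1 / (ev + lambda)
    Q %*% (d * crossprod(Q, rhs))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict fMRI time series from a fitted encoding model
#'
#' Applies the model's recorded standardization to the new design,
#' multiplies by the learned weights, and inverse-transforms back to the
#' original fMRI scale. A design equal to the recorded column means
#' therefore predicts the recorded voxel means.
#'
#' @param object an \linkS4class{EncodingModel}.
#' @param X a \linkS4class{DesignMatrix} or matrix with the same column
#'   layout the model was trained on.
#' @param rescale if FALSE, return predictions on the standardized scale.
#' @return T x V matrix of predicted responses.
#' @export
setMethod("predict", "EncodingModel", function(object, X,
                                               rescale = TRUE) {
  if (is(X, "DesignMatrix")) {
    mine <- object@columnIndex
    theirs <- X@columnIndex
    bad <- which(mine$feature != theirs$feature | mine$lag != theirs$lag)
    if (nrow(mine) != nrow(theirs))
      stop("design has ", nrow(theirs), " columns but the model expects ",
           nrow(mine), call. = FALSE)
    if (length(bad))
      stop("design columns do not match the model at positions ",
           paste(utils::head(bad, 5), collapse = ", "), " (",
           paste(utils::head(paste0(theirs$feature[bad], ".lag",
                                    theirs$lag[bad]), 5),
                 collapse = ", "), ")", call. = FALSE)
    X <- X@values
  }
  X <- as.matrix(X)
  stopIfNot(ncol(X) == ncol(object@weights),
            "column count does not match the model")
  Xs <- applyStandardization(X, object@standardization$X)
  P <- Xs %*% t(object@weights)
  if (rescale)
    P <- applyStandardization(P, object@standardization$Y, invert = TRUE)
  P
})

#' Extract one voxel's temporal response signature for one feature
#'
#' @param model an \linkS4class{EncodingModel}.
#' @param voxel voxel index.
#' @param feature feature name.
#' @param rescale if TRUE (default), return the weights on the original
#'   input scale (undo the fitting-time standardization) so they are
#'   comparable with generative ground truth.
#' @return Numeric vector of L weights ordered by lag.
#' @export
extractSignature <- function(model, voxel, feature, rescale = TRUE) {
  stopIfNot(is(model, "EncodingModel"), "model must be an EncodingModel")
  stopIfNot(voxel >= 1 && voxel <= nrow(model@weights),
            "voxel index out of range")
  rows <- model@columnIndex$feature == feature
  if (!any(rows))
    stop("unknown feature '", feature, "'; available: ",
         paste(unique(model@columnIndex$feature), collapse = ", "),
         call. = FALSE)
  cols <- model@columnIndex$column[rows][order(model@columnIndex$lag[rows])]
  w <- model@weights[voxel, cols]
  if (rescale) {
    sx <- model@standardization$X$scale[cols]
    sy <- model@standardization$Y$scale[voxel]
    w <- w * sy / sx
  }
  unname(w)
}

#' Destandardized weight matrix
#'
#' Returns the full V x (F*L) weight matrix mapped back to the original
#' input/output scales, for comparison with generative ground truth.
#'
#' @param model an \linkS4class{EncodingModel}.
#' @return V x (F*L) matrix.
#' @export
rawWeights <- function(model) {
  sx <- model@standardization$X$scale
  sy <- model@standardization$Y$scale
  sweep(model@weights, 2, sx, "/") * sy
}
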