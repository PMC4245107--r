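# Shared fixtures, built in code at test time.

# A small deterministic story: nWords words at a fixed rate, explicit
# feature matrix so expected values can be computed by hand.
tinyStory <- function(nWords = 8, wordPeriod = 0.5,
                      features = NULL, featureSets = list()) {
  if (is.null(features))
    features <- matrix(seq_len(nWords * 2), nWords, 2,
                       dimnames = list(NULL, c("f1", "f2")))
  AnnotatedStory(words = rep("word", nWords),
                 onsets = (seq_len(nWords) - 1) * wordPeriod,
                 features = features,
                 featureSets = featureSets,
                 wordDuration = wordPeriod)
}

# Wrap a plain matrix as a FeatureTimeSeries.
makeFts <- function(values, tr = 2, featureNames = NULL) {
  values <- as.matrix(values)
  if (is.null(featureNames))
    featureNames <- colnames(values) %||%
      paste0("f", seq_len(ncol(values)))
  colnames(values) <- featureNames
  new("FeatureTimeSeries", values = values, tr = tr,
      featureNames = featureNames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subjects whose fMRI is pure white noise on a small grid, for evaluation
# edge-case tests that bypass the full generator.
noiseSubjects <- function(nSubjects = 2, T = 200, V = 24, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(nSubjects), function(s) {
    g <- expand.grid(x = 1:4, y = 1:3, z = seq_len(ceiling(V / 12)))
    SubjectData(sprintf("n%02d", s),
                fmri = matrix(rnorm(T * V), T, V),
                coords = as.matrix(g[seq_len(V), ]) * 3)
  }))
}

# Direct (dense-solve) ridge oracle, independent of the eigen-based path.
ridgeOracle <- function(X, y, lambda) {
  solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y))
}
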