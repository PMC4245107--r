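test_that("ridge solutions match hand-derived values", {
  X <- matrix(c(1, 2), 2, 1)
  y <- c(2, 4)
  # unpenalized least squares: w = 2 exactly
  m0 <- fitRidge(X, y, penaltyGrid = 0, standardize = FALSE)
  expect_equal(unname(weights(m0)[1, 1]), 2, tolerance = 1e-12)
  # (X'X + 2)^{-1} X'y = 10 / 7
  m2 <- fitRidge(X, y, penaltyGrid = 2, standardize = FALSE)
  expect_equal(unname(weights(m2)[1, 1]), 10 / 7, tolerance = 1e-12)
  # an essentially infinite penalty shrinks weights to zero
  mInf <- fitRidge(X, y, penaltyGrid = 1e12, standardize = FALSE)
  expect_lt(abs(weights(mInf)[1, 1]), 1e-9)
})

test_that("fitted weights equal the direct normal-equations solution", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    p <- sample(2:8, 1)
    lam <- 10^runif(1, -2, 3)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fitRidge(X, y, penaltyGrid = lam, standardize = FALSE)
    expect_lt(max(abs(weights(fit)[1, ] - ridgeOracle(X, y, lam))), 1e-8)
  }
})

test_that("weight norm shrinks monotonically with the penalty", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  norms <- sapply(10^(-2:6), function(lam)
    sum(weights(fitRidge(X, y, penaltyGrid = lam,
                         standardize = FALSE))^2))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("inputs with NaN or too few rows are rejected", {
  expect_error(fitRidge(matrix(c(1, NaN), 2, 1), c(1, 2),
                        penaltyGrid = 1), "NaN")
  expect_error(fitRidge(matrix(rnorm(4), 4, 1), rnorm(4),
                        penaltyGrid = c(1, 10), innerFolds = 5),
               "innerFolds")
})

test_that("pure-noise voxels receive penalties at the top of the grid", {
  set.seed(11)
  T <- 200
  X <- matrix(rnorm(T * 8), T, 8)
  Y <- matrix(rnorm(T * 50), T, 50)          # no relation to X
  fit <- fitRidge(X, Y, penaltyGrid = 10^(0:7), innerFolds = 5)
  topTwo <- 10^(6:7)
  expect_gte(mean(penalties(fit) %in% topTwo), 0.9)
})

test_that("prediction inverts standardization and flags layout mismatch", {
  set.seed(3)
  fts <- makeFts(matrix(rnorm(60), 30, 2,
                        dimnames = list(NULL, c("a", "b"))))
  X <- buildLaggedDesign(fts, 4)
  Y <- matrix(rnorm(30 * 3), 30, 3) + 5
  fit <- fitRidge(X, Y, penaltyGrid = 10, standardize = TRUE)
  # a design at the recorded column means predicts the voxel means
  Xbar <- matrix(rep(fit@standardization$X$center, each = 4), 4,
                 ncol(values(X)), byrow = FALSE)
  expect_equal(predict(fit, Xbar),
               matrix(rep(colMeans(Y), each = 4), 4, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # column layout mismatches are named
  fts2 <- makeFts(matrix(rnorm(60), 30, 2,
                         dimnames = list(NULL, c("zz", "b"))))
  expect_error(predict(fit, buildLaggedDesign(fts2, 4)), "zz")
})

test_that("a single lagged weight acts as an impulse response", {
  # one feature, one lag, weight 2: impulse at t contributes 2 at t + 1
  x <- makeFts(matrix(c(0, 1, 0), 3, 1, dimnames = list(NULL, "f")))
  X <- buildLaggedDesign(x, 1)
  model <- new("EncodingModel",
               weights = matrix(2, 1, 1), penalties = 0,
               columnIndex = X@columnIndex, lagSeconds = X@lagSeconds,
               standardization = list(
                 X = storyEncoding:::identityStandardization(1),
                 Y = storyEncoding:::identityStandardization(1)))
  expect_equal(unname(predict(model, X)[, 1]), c(0, 0, 2))
})

test_that("full-rank unpenalized fit interpolates the training data", {
  set.seed(9)
  X <- matrix(rnorm(16), 4, 4)               # T = F * L
  Y <- matrix(rnorm(8), 4, 2)
  fit <- fitRidge(X, Y, penaltyGrid = 0, standardize = FALSE)
  expect_equal(X %*% t(weights(fit)), Y, tolerance = 1e-8)
})

test_that("response signatures are recovered from synthetic data", {
  story <- generateStory(nWords = 4000, nFeatures = 6, seed = 21)
  sim <- generateSubjects(story, nSubjects = 1, snr = 1, jitterMm = 0,
                          gridDim = c(3, 2, 2), seed = 22)
  X <- buildLaggedDesign(resampleToTr(story, 2), 4)
  fit <- fitRidge(X, sim$subjects[[1]]@fmri, penaltyGrid = 10^(0:7),
                  innerFolds = 5)
  truth <- sim$truth@weights[[1]]
  driven <- which(rowSums(abs(truth)) > 0)
  feat <- sim$truth@columnIndex$feature[
    which(truth[driven[1], ] != 0)[1]]
  est <- extractSignature(fit, driven[1], feat)
  cols <- sim$truth@columnIndex$column[
    sim$truth@columnIndex$feature == feat]
  expect_gt(cor(est, truth[driven[1], cols]), 0.95)
})

test_that("signatures of silent features and untrained models are zero", {
  set.seed(13)
  # feature 'b' never occurs: its ridge signature is exactly zero
  v <- cbind(a = rnorm(40), b = 0)
  X <- buildLaggedDesign(makeFts(v), 2)
  fit <- fitRidge(X, rnorm(40), penaltyGrid = 5, standardize = FALSE)
  expect_equal(extractSignature(fit, 1, "b"), c(0, 0))
  expect_error(extractSignature(fit, 1, "zz"), "unknown feature")
  zeroModel <- new("EncodingModel",
                   weights = matrix(0, 1, 4), penalties = 1,
                   columnIndex = X@columnIndex,
                   lagSeconds = X@lagSeconds,
                   standardization = list(
                     X = storyEncoding:::identityStandardization(4),
                     Y = storyEncoding:::identityStandardization(1)))
  expect_equal(extractSignature(zeroModel, 1, "a"), c(0, 0))
})
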