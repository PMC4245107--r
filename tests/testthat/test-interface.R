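test_that("NIfTI volumes round-trip through write and read", {
  set.seed(91)
  g <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  keep <- sample(nrow(g), 20)                # 20-voxel mask in a 4x4x4 grid
  coords <- as.matrix(g[keep, ]) * 3 + c(9, -6, 12)
  sub <- SubjectData("rt", matrix(rnorm(10 * 20), 10, 20), coords,
                     voxelSize = 3)
  d <- withr::local_tempdir()
  nii <- file.path(d, "rt.nii.gz")
  msk <- file.path(d, "rt_mask.nii.gz")
  writeFmriNifti(sub, nii, msk)
  back <- readFmri(nii, mask = msk)
  # same voxels, possibly reordered by mask scan order
  ord <- match(do.call(paste, as.data.frame(round(voxelCoords(sub)))),
               do.call(paste, as.data.frame(round(voxelCoords(back)))))
  expect_false(anyNA(ord))
  expect_equal(fmriData(back)[, ord], fmriData(sub), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(voxelCoords(back)[ord, ], voxelCoords(sub),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(ncol(fmriData(back)), 20L)    # mask-count oracle
  expect_equal(nrow(fmriData(back)), 10L)
})

test_that("voxel coordinates come from the affine", {
  g <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  coords <- as.matrix(g) * 3
  sub <- SubjectData("aff", matrix(rnorm(5 * 27), 5, 27), coords)
  d <- withr::local_tempdir()
  writeFmriNifti(sub, file.path(d, "a.nii.gz"),
                 file.path(d, "a_mask.nii.gz"))
  img <- RNifti::readNifti(file.path(d, "a.nii.gz"))
  aff <- RNifti::xform(img)
  back <- readFmri(file.path(d, "a.nii.gz"),
                   mask = file.path(d, "a_mask.nii.gz"))
  ijk1 <- rbind(t(as.matrix(g)), 1)          # 0-based voxel indices
  expected <- t(aff %*% ijk1)[, 1:3]
  key <- function(m) do.call(paste, as.data.frame(round(m, 3)))
  expect_setequal(key(voxelCoords(back)), key(expected))
})

test_that("matrix + sidecar TSV round-trips", {
  sub <- noiseSubjects(nSubjects = 1, T = 15, V = 12)[[1]]
  d <- withr::local_tempdir()
  writeFmriTsv(sub, file.path(d, "s.tsv"), file.path(d, "s_coords.tsv"))
  back <- readFmri(file.path(d, "s.tsv"),
                   coords = file.path(d, "s_coords.tsv"), voxelSize = 3)
  expect_equal(fmriData(back), fmriData(sub), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(voxelCoords(back), voxelCoords(sub), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(readFmri(file.path(d, "s.tsv")), "sidecar")
})

test_that("searchlight maps round-trip and count significant centres", {
  map <- expand.grid(x = seq(0, 9, 3), y = seq(0, 9, 3), z = 0)
  map$featureSet <- rep(c("visual", "syntax"), each = 8)
  map$nVoxels <- 20
  map$nTrials <- 60
  map$accuracy <- runif(16, 0.4, 1)
  map$p <- runif(16, 0.001, 1)
  map$q <- fdrBH(map$p)$qvalues
  map$significant <- map$q <= 0.05
  map$missing <- FALSE
  res <- new("SearchlightResult", map = map, edgeVoxels = 5L,
             voxelSize = 3, seed = 1)
  d <- withr::local_tempdir()
  paths <- writeMap(res, d, prefix = "m")
  expect_true(file.exists(file.path(d, "m.tsv")))
  accVol <- RNifti::readNifti(file.path(d, "m_visual_accuracy.nii.gz"))
  sel <- map$featureSet == "visual"
  expect_equal(sort(as.vector(accVol)[!is.nan(as.vector(accVol))]),
               sort(map$accuracy[sel]), tolerance = 1e-6)
  sig <- as.vector(RNifti::readNifti(
    file.path(d, "m_visual_significant.nii.gz")))
  expect_equal(sum(sig[!is.nan(sig)]), sum(map$significant[sel]))
  # per-feature-set files are independent
  expect_true(file.exists(file.path(d, "m_syntax_accuracy.nii.gz")))
  unlink(file.path(d, "m_syntax_accuracy.nii.gz"))
  expect_equal(
    sort(as.vector(RNifti::readNifti(
      file.path(d, "m_visual_accuracy.nii.gz")))[
        !is.nan(as.vector(accVol))]),
    sort(map$accuracy[sel]), tolerance = 1e-6)
  # centres outside a declared template are an error
  expect_error(writeMap(res, d, template = list(origin = c(0, 0, 0),
                                                dim = c(2, 2, 1))),
               "outside")
})

test_that("the CLI simulates deterministically and classifies", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  args <- c("simulate", "--seed", "4", "--nWords", "1600")
  expect_equal(cliMain(c(args, "--out", d1)), 0L)
  expect_equal(cliMain(c(args, "--out", d2)), 0L)
  # config.yaml stores the (distinct) output paths; data files must match
  for (f in c("story.tsv", "sub01.tsv", "sub01_coords.tsv",
              "feature_sets.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  out <- withr::local_tempdir()
  log <- capture.output(
    status <- cliMain(c("classify", "--data", d1, "--out", out,
                        "--seed", "5")))
  expect_equal(status, 0L)
  expect_match(log, "accuracy", all = FALSE)
  expect_true(file.exists(file.path(out, "classification.yaml")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  acc <- yaml::read_yaml(file.path(out, "classification.yaml"))$accuracy
  expect_gte(acc, 0.5)                       # snr 1 signal is decodable
})

test_that("the CLI null + report pipeline controls the map", {
  d <- withr::local_tempdir()
  expect_equal(cliMain(c("simulate", "--seed", "6", "--nWords", "1600",
                         "--out", d)), 0L)
  out <- withr::local_tempdir()
  capture.output({
    expect_equal(cliMain(c("searchlight", "--data", d, "--out", out,
                           "--feature-set", "visual", "--stride", "4",
                           "--seed", "7")), 0L)
    expect_equal(cliMain(c("null", "--data", d, "--out", out,
                           "--feature-set", "visual",
                           "--permutations", "5", "--seed", "8")), 0L)
    expect_equal(cliMain(c("report", "--map",
                           file.path(out, "searchlight.tsv"),
                           "--null-file",
                           file.path(out, "null_accuracies.tsv"),
                           "--out", out)), 0L)
  })
  rep <- read.delim(file.path(out, "report.tsv"))
  expect_true(all(rep$p[!rep$missing] > 0 & rep$p[!rep$missing] <= 1))
  expect_true(all(rep$q[!rep$missing] >= rep$p[!rep$missing] - 1e-12))
})

test_that("usage errors exit with status 2", {
  expect_equal(suppressMessages(cliMain("frobnicate")), 2L)
  expect_equal(suppressMessages(cliMain(c("simulate", "--seed"))), 2L)
  expect_equal(suppressMessages(cliMain(character(0))), 2L)
})
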