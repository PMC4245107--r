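test_that("resampling sums all words presented within one TR", {
  story <- tinyStory(nWords = 4,
                     features = matrix(c(5, 3, 4, 2), 4, 1,
                                       dimnames = list(NULL, "f")))
  fts <- resampleToTr(story, tr = 2)
  expect_equal(nrow(values(fts)), 1L)        # four 0.5 s words in one TR
  expect_equal(unname(values(fts)[1, "f"]), 14)      # 5 + 3 + 4 + 2
})

test_that("boundary onsets go to the later bin and zero rows pad the run", {
  story <- AnnotatedStory(words = c("a", "b"), onsets = c(0, 2),
                          features = matrix(c(1, 1), 2, 1,
                                            dimnames = list(NULL, "f")),
                          duration = 8)
  fts <- resampleToTr(story, tr = 2)
  expect_equal(unname(values(fts)[, 1]), c(1, 1, 0, 0))

  zero <- tinyStory(features = matrix(0, 8, 3,
                                      dimnames = list(NULL,
                                                      c("a", "b", "c"))))
  expect_true(all(values(resampleToTr(zero, 2)) == 0))
  expect_equal(dim(values(resampleToTr(zero, 2))),
               c(ceiling(8 * 0.5 / 2), 3))
})

test_that("resampling conserves column totals for any tr", {
  set.seed(42)
  for (tr in c(0.5, 1, 2, 3.3)) {
    story <- tinyStory(nWords = 23,
                       features = matrix(rnorm(23 * 4), 23, 4))
    fts <- resampleToTr(story, tr)
    expect_equal(colSums(values(fts)), colSums(story@features),
                 ignore_attr = TRUE)
  }
})

test_that("resampling at the word period copies one word per row", {
  story <- tinyStory(nWords = 6)
  fts <- resampleToTr(story, tr = 0.5)
  expect_equal(unname(values(fts)), unname(story@features))
})

test_that("resampling rejects bad onsets and bad tr", {
  story <- tinyStory(nWords = 4)
  story@duration <- 1.2                      # word 4 at 1.5 s is outside
  expect_error(resampleToTr(story, 2), "word\\(s\\) 4")
  expect_error(resampleToTr(tinyStory(), tr = -1), "tr")
})

test_that("feature-set selection extracts named columns in order", {
  feats <- matrix(rnorm(40), 8, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
  story <- tinyStory(features = feats,
                     featureSets = list(visual = "f3",
                                        pair = c("f4", "f2"),
                                        all = paste0("f", 1:5)))
  fts <- resampleToTr(story, 2)
  vis <- selectFeatureSet(fts, "visual", story)
  expect_equal(ncol(values(vis)), 1L)
  expect_equal(values(vis)[, 1], values(fts)[, "f3"])

  pair <- selectFeatureSet(fts, "pair", story)
  expect_equal(featureNames(pair), c("f4", "f2"))
  expect_equal(values(pair), values(fts)[, c("f4", "f2")])

  full <- selectFeatureSet(fts, "all", story)
  expect_equal(values(full), values(fts))
  # selecting the full set twice is idempotent
  expect_equal(values(selectFeatureSet(full, "all", story)), values(full))

  expect_error(selectFeatureSet(fts, "nope", story), "visual.*pair.*all")
})

test_that("word length counts alphabetic characters only", {
  expect_equal(annotateWordLength(c("Harry", "a", "broom-stick")),
               c(5L, 1L, 10L))
  expect_equal(annotateWordLength("don't"), 4L)
  expect_error(annotateWordLength(character(0)), "non-empty")
})

test_that("annotation TSV and feature-set YAML round-trip", {
  story <- tinyStory(nWords = 5,
                     features = matrix(rnorm(10), 5, 2,
                                       dimnames = list(NULL,
                                                       c("len", "pos"))),
                     featureSets = list(visual = "len", syntax = "pos"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeWordAnnotations(story, tsv)
  back <- readWordAnnotations(tsv)
  expect_equal(back@onsets, story@onsets)
  expect_equal(back@duration, story@duration)
  expect_equal(back@features, story@features, tolerance = 1e-12)

  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(featureSets(story), yml)
  featureSets(back) <- readFeatureSets(yml)
  expect_equal(featureSets(back), featureSets(story))
})

test_that("story invariants are enforced", {
  expect_error(AnnotatedStory("a", onsets = -1,
                              features = matrix(1, 1, 1)), "non-negative")
  expect_error(AnnotatedStory(c("a", "b"), onsets = c(1, 1),
                              features = matrix(1, 2, 1)), "increasing")
  expect_error(AnnotatedStory("a", 0, matrix(NaN, 1, 1)), "finite")
  expect_error(
    AnnotatedStory("a", 0, matrix(1, 1, 1, dimnames = list(NULL, "f")),
                   featureSets = list(s = "missing")), "unknown")
})

test_that("the packaged example annotation files load", {
  tsv <- system.file("extdata", "example_story.tsv",
                     package = "storyEncoding")
  yml <- system.file("extdata", "example_feature_sets.yaml",
                     package = "storyEncoding")
  story <- readWordAnnotations(tsv)
  featureSets(story) <- readFeatureSets(yml)
  expect_equal(length(story@words), 10L)
  expect_equal(story@duration, 6)
  fts <- resampleToTr(story, 2)
  expect_equal(nrow(values(fts)), 3L)
  expect_equal(unname(values(fts)[1, "wordLength"]), 3 + 3 + 3 + 5)
  expect_equal(unname(values(selectFeatureSet(fts, "discourse",
                                              story))[, 1]),
               c(0, 1, 0))
})
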