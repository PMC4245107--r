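#' Collapse word-level annotations onto the fMRI sampling grid
#'
#' Words are presented much faster (one per 0.5 s) than fMRI volumes are
#' acquired (one per TR = 2 s), so the per-word feature vectors of all
#' words whose onset falls inside a TR are summed into that TR's row.
#' Words exactly on a TR boundary belong to the later bin (half-open
#' intervals \code{[t*tr, (t+1)*tr)}). The number of rows is
#' \code{ceiling(duration / tr)} using the story's declared run length, so
#' trailing silent TRs appear as zero rows. Column sums are conserved:
#' the total magnitude of each feature over the run is unchanged by
#' resampling.
#'
#' @param story an \linkS4class{AnnotatedStory}.
#' @param tr sampling period in seconds (default 2).
#' @return A \linkS4class{FeatureTimeSeries}.
#' @examples
#' story <- AnnotatedStory(words = c("the", "tall", "old", "wizard"),
#'                         onsets = c(0, 0.5, 1, 1.5),
#'                         features = matrix(1, 4, 1,
#'                                           dimnames = list(NULL, "len")))
#' resampleToTr(story, tr = 2)  # all four words summed into row 1
#' @export
resampleToTr <- function(story, tr = 2) {
  stopIfNot(is(story, "AnnotatedStory"), "story must be an AnnotatedStory")
  stopIfNot(is.numeric(tr) && length(tr) == 1 && tr > 0,
            "tr must be a positive scalar")
  onsets <- story@onsets
  beyond <- which(onsets >= story@duration)
  if (length(beyond))
    stop("word(s) ", paste(beyond, collapse = ", "),
         " have onsets at or beyond the declared run length (",
         story@duration, " s)", call. = FALSE)
  nT <- as.integer(ceiling(story@duration / tr))
  F <- ncol(story@features)
  vals <- matrix(0, nT, F, dimnames = list(NULL, story@featureNames))
  if (length(onsets)) {
    bin <- floor(onsets / tr) + 1L   # boundary onsets go to the later bin
    rs <- rowsum(story@features, bin)
    vals[as.integer(rownames(rs)), ] <- rs
  }
  new("FeatureTimeSeries", values = vals, tr = tr,
      featureNames = story@featureNames)
}

#' Restrict a feature time series to one named feature set
#'
#' Representation mapping annotates the text with only one type of story
#' feature at a time; this pulls out the columns belonging to a named set,
#' in the order the set declares them, leaving values untouched.
#'
#' @param fts a \linkS4class{FeatureTimeSeries}.
#' @param setName name of a set in \code{featureSets(story)}.
#' @param story the \linkS4class{AnnotatedStory} declaring the sets.
#' @return A \linkS4class{FeatureTimeSeries} with the set's columns only.
#' @export
selectFeatureSet <- function(fts, setName, story) {
  stopIfNot(is(fts, "FeatureTimeSeries"),
            "fts must be a FeatureTimeSeries")
  sets <- featureSets(story)
  if (!setName %in% names(sets))
    stop("unknown feature set '", setName, "'; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  keep <- sets[[setName]]
  idx <- match(keep, fts@featureNames)
  if (anyNA(idx))
    stop("feature set '", setName, "' names columns absent from the ",
         "series: ", paste(keep[is.na(idx)], collapse = ", "),
         call. = FALSE)
  new("FeatureTimeSeries",
      values = fts@values[, idx, drop = FALSE],
      tr = fts@tr, featureNames = keep)
}

#' Word-length feature column
#'
#' Counts alphabetic characters per token (hyphens, apostrophes and other
#' punctuation excluded), the low-level visual word property used as the
#' canonical "visual" feature.
#'
#' @param words non-empty character vector of tokens.
#' @return Integer vector, one count per word.
#' @examples
#' annotateWordLength(c("Harry", "a", "broom-stick"))  # 5 1 10
#' @export
annotateWordLength <- function(words) {
  stopIfNot(is.character(words) && length(words) > 0,
            "words must be a non-empty character vector")
  vapply(words,
         function(w) sum(strsplit(w, "")[[1]] %in% c(letters, LETTERS)),
         integer(1), USE.NAMES = FALSE)
}

#' Read word-level annotations from TSV
#'
#' Expected layout: a header row \code{token onset <feature...>}, one row
#' per presented word, onsets in seconds. An optional comment line
#' \code{# duration: <seconds>} before the header declares the run length.
#'
#' @param path TSV file path.
#' @param wordDuration presentation time per word in seconds (default 0.5).
#' @return An \linkS4class{AnnotatedStory} (feature sets empty; attach them
#'   with \code{\link{readFeatureSets}} and \code{featureSets<-}).
#' @export
readWordAnnotations <- function(path, wordDuration = 0.5) {
  first <- readLines(path, n = 1)
  duration <- NULL
  if (grepl("^#\\s*duration:", first))
    duration <- as.numeric(sub("^#\\s*duration:\\s*", "", first))
  tab <- utils::read.delim(path, comment.char = "#",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopIfNot(all(c("token", "onset") %in% names(tab)),
            "annotation TSV must have 'token' and 'onset' columns")
  featCols <- setdiff(names(tab), c("token", "onset"))
  AnnotatedStory(words = as.character(tab$token),
                 onsets = as.numeric(tab$onset),
                 features = as.matrix(tab[, featCols, drop = FALSE]),
                 featureNames = featCols,
                 wordDuration = wordDuration,
                 duration = duration)
}

#' Read a feature-set grouping file (YAML)
#'
#' Maps set names (e.g. visual, syntax, semantics, discourse) to lists of
#' feature column names.
#'
#' @param path YAML file path.
#' @return Named list of character vectors.
#' @export
readFeatureSets <- function(path) {
  sets <- yaml::read_yaml(path)
  stopIfNot(is.list(sets) && !is.null(names(sets)),
            "feature-set file must map set names to feature lists")
  lapply(sets, as.character)
}
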