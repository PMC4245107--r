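#' Read one subject's fMRI run
#'
#' Two on-disk layouts are supported: a 4D NIfTI volume with a 3D mask
#' volume (voxel coordinates are derived from the NIfTI affine, voxel-
#' centre convention, RAS+ mm), or a plain-text T x V matrix TSV with a
#' V x 3 coordinate sidecar TSV -- the latter keeps desk-scale analyses
#' free of volumetric files.
#'
#' @param path path to a \code{.nii}/\code{.nii.gz} 4D volume or a
#'   \code{.tsv} matrix file.
#' @param mask path to a mask volume (NIfTI input only); voxels with
#'   nonzero mask are kept.
#' @param coords path to the coordinate sidecar TSV (TSV input only),
#'   columns x, y, z in mm.
#' @param voxelSize voxel edge in mm (TSV input; for NIfTI it is taken
#'   from the affine).
#' @param subjectId identifier (default: file name).
#' @return A \linkS4class{SubjectData}.
#' @export
readFmri <- function(path, mask = NULL, coords = NULL, voxelSize = 3,
                     subjectId = NULL) {
  if (is.null(subjectId))
    subjectId <- sub("\\.(nii(\\.gz)?|tsv)$", "", basename(path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    stopIfNot(length(dim(arr)) == 4, "expected a 4D NIfTI volume")
    aff <- RNifti::xform(img)
    if (any(!is.finite(aff)) || abs(det(aff[1:3, 1:3])) < 1e-12)
      stop("NIfTI affine is missing or singular", call. = FALSE)
    stopIfNot(!is.null(mask), "a mask volume is required for NIfTI input")
    mk <- as.array(RNifti::readNifti(mask)) != 0
    stopIfNot(identical(dim(mk), dim(arr)[1:3]),
              "mask dimensions do not match the volume")
    idx <- which(mk, arr.ind = TRUE)
    d3 <- prod(dim(arr)[1:3])
    flat <- matrix(arr, d3, dim(arr)[4])
    lin <- idx[, 1] + (idx[, 2] - 1L) * dim(arr)[1] +
      (idx[, 3] - 1L) * dim(arr)[1] * dim(arr)[2]
    fmri <- t(flat[lin, , drop = FALSE])
    cmm <- t(aff %*% rbind(t(idx - 1), 1))[, 1:3, drop = FALSE]
    vs <- sqrt(sum(aff[1:3, 1]^2))
    SubjectData(subjectId, fmri, cmm, voxelSize = vs)
  } else {
    fmri <- as.matrix(utils::read.delim(path, check.names = FALSE))
    stopIfNot(!is.null(coords),
              "a coordinate sidecar TSV is required for matrix input")
    cmm <- as.matrix(utils::read.delim(coords))[, c("x", "y", "z")]
    SubjectData(subjectId, fmri, cmm, voxelSize = voxelSize)
  }
}

#' Write one subject's fMRI run
#'
#' \code{writeFmriNifti} places the voxels back on their integer grid
#' (derived from the coordinates and voxel size), writes a 4D volume and
#' a mask volume with a diagonal affine mapping voxel indices to the
#' original mm coordinates. \code{writeFmriTsv} writes the plain-text
#' matrix + sidecar layout.
#'
#' @param subject a \linkS4class{SubjectData}.
#' @param path output volume path (\code{.nii} or \code{.nii.gz}).
#' @param maskPath output mask path.
#' @return Invisibly, the written paths.
#' @export
writeFmriNifti <- function(subject, path, maskPath) {
  vs <- subject@voxelSize
  lo <- apply(subject@coords, 2, min)
  idx <- round(sweep(subject@coords, 2, lo) / vs) + 1L
  dims <- apply(idx, 2, max)
  T <- nrow(subject@fmri)
  lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] +
    (idx[, 3] - 1L) * dims[1] * dims[2]
  arr <- array(0, c(dims, T))
  flat <- matrix(arr, prod(dims), T)
  flat[lin, ] <- t(subject@fmri)
  arr <- array(flat, c(dims, T))
  mk <- array(0L, dims)
  mk[lin] <- 1L
  aff <- structure(rbind(cbind(diag(3) * vs, lo), c(0, 0, 0, 1)),
                   code = 2L)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, vs, vs, 1)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  RNifti::writeNifti(img, path)
  mimg <- RNifti::asNifti(mk)
  RNifti::pixdim(mimg) <- c(vs, vs, vs)
  mimg <- RNifti::`sform<-`(mimg, aff)
  mimg <- RNifti::`qform<-`(mimg, aff)
  RNifti::writeNifti(mimg, maskPath)
  invisible(c(path, maskPath))
}

#' @rdname writeFmriNifti
#' @param coordsPath sidecar TSV path for the coordinates.
#' @export
writeFmriTsv <- function(subject, path, coordsPath) {
  m <- subject@fmri
  colnames(m) <- paste0("v", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cc <- data.frame(x = subject@coords[, 1], y = subject@coords[, 2],
                   z = subject@coords[, 3])
  utils::write.table(cc, coordsPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(path, coordsPath))
}

#' Write word-level annotations to TSV
#'
#' Inverse of \code{\link{readWordAnnotations}}: header
#' \code{token onset <features>}, preceded by a \code{# duration:} line
#' declaring the run length.
#'
#' @param story an \linkS4class{AnnotatedStory}.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
writeWordAnnotations <- function(story, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration: %g", story@duration), con)
  tab <- data.frame(token = story@words, onset = story@onsets,
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(story@features))
  utils::write.table(tab, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a searchlight map to disk
#'
#' Always writes a TSV with one row per (centre, feature set); when a
#' template is available (derived from the map's own centre grid by
#' default) it additionally writes, per feature set, an accuracy volume,
#' a q-value volume and a binary significance volume as NIfTI, with NaN
#' at missing centres.
#'
#' @param result a \linkS4class{SearchlightResult}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "map").
#' @param template optional list(dim, origin) in voxel/mm units bounding
#'   the volumes; centres falling outside it are an error.
#' @param writeVolumes write NIfTI volumes as well as the TSV (default
#'   TRUE).
#' @return Invisibly, a character vector of written paths.
#' @export
writeMap <- function(result, dir, prefix = "map", template = NULL,
                     writeVolumes = TRUE) {
  stopIfNot(is(result, "SearchlightResult"),
            "result must be a SearchlightResult")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- resultMap(result)
  paths <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(m, paths, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!writeVolumes) return(invisible(paths))
  vs <- result@voxelSize
  cen <- unique(m[, c("x", "y", "z")])
  if (is.null(template)) {
    origin <- apply(cen, 2, min)
    dims <- as.integer(round((apply(cen, 2, max) - origin) / vs)) + 1L
  } else {
    origin <- template$origin
    dims <- as.integer(template$dim)
  }
  idxAll <- round(sweep(as.matrix(m[, c("x", "y", "z")]), 2, origin) / vs) + 1L
  if (any(idxAll < 1) || any(sweep(idxAll, 2, dims) > 0))
    stop("map centre outside the template bounds", call. = FALSE)
  aff <- structure(rbind(cbind(diag(3) * vs, origin), c(0, 0, 0, 1)),
                   code = 2L)
  for (nm in unique(m$featureSet)) {
    sel <- m$featureSet == nm
    idx <- idxAll[sel, , drop = FALSE]
    lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] +
      (idx[, 3] - 1L) * dims[1] * dims[2]
    for (what in c("accuracy", "q", "significant")) {
      vol <- array(NaN, dims)
      v <- m[[what]][sel]
      vol[lin] <- if (is.logical(v)) as.numeric(v) else v
      img <- RNifti::asNifti(vol)
      RNifti::pixdim(img) <- c(vs, vs, vs)
      img <- RNifti::`sform<-`(img, aff)
      img <- RNifti::`qform<-`(img, aff)
      p <- file.path(dir, paste0(prefix, "_", nm, "_", what, ".nii.gz"))
      RNifti::writeNifti(img, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
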