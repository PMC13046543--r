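# NIfTI I/O and masking. Voxel ordering is a pure function of the mask:
# ascending linear index in array-native (column-major) order. Files are
# float32 on disk, float64 in memory.

#' Load a masked 4-D BOLD series
#'
#' Reads a 4-D NIfTI volume and a 3-D mask sharing its grid, and returns the
#' in-mask data in time-by-voxel layout. Column j is the time series of the
#' j-th in-mask voxel in ascending linear-index order. The TR is taken from the
#' 4th pixdim entry of the volume header. By default every voxel time series is
#' z-scored over time (mean 0, SD 1), the usual precondition for ICA; pass
#' \code{normalize = FALSE} for raw intensities.
#'
#' @param volumePath path to a 4-D NIfTI file.
#' @param maskPath path to a 3-D NIfTI mask (nonzero = in mask).
#' @param normalize z-score each voxel time series over time (default TRUE).
#' @param subjectId subject identifier (default: volume file name).
#' @return A \linkS4class{BoldSeries}.
#' @export
loadMaskedSeries <- function(volumePath, maskPath, normalize = TRUE,
                             subjectId = NULL) {
  vol <- RNifti::readNifti(volumePath)
  msk <- RNifti::readNifti(maskPath)
  dv <- dim(vol)
  dm <- dim(msk)
  if (length(dv) != 4L)
    stop(sprintf("expected a 4-D volume, got dimensions [%s]",
                 paste(dv, collapse = ", ")))
  if (length(dm) != 3L || !all(dv[1:3] == dm))
    stop(sprintf("volume grid [%s] does not match mask grid [%s]",
                 paste(dv[1:3], collapse = ", "), paste(dm, collapse = ", ")))
  maskIdx <- which(as.array(msk) != 0)
  if (length(maskIdx) == 0L) stop("mask is empty (no nonzero voxels)")
  T <- dv[4]
  flat <- matrix(as.numeric(vol), prod(dv[1:3]), T)
  data <- t(flat[maskIdx, , drop = FALSE])       # T x V
  badVox <- colSums(!is.finite(data)) > 0
  if (any(badVox))
    stop(sprintf("%d in-mask voxel(s) contain non-finite values", sum(badVox)))
  if (normalize) {
    sds <- apply(data, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("%d in-mask voxel(s) have constant time series and cannot be z-scored",
                   sum(sds == 0)))
    data <- scale(data)
    attr(data, "scaled:center") <- NULL
    attr(data, "scaled:scale") <- NULL
  }
  tr <- RNifti::pixdim(vol)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(volumePath))
  BoldSeries(data, trSeconds = tr, maskIndices = maskIdx,
             gridShape = dv[1:3], subjectId = subjectId)
}

#' Save component maps as a NIfTI volume
#'
#' Writes an N x V matrix of maps into a 4-D NIfTI file (4th dimension =
#' component; a singleton for N = 1). Out-of-mask voxels are written as 0;
#' data are stored as float32.
#'
#' @param maps numeric N x V matrix; V must equal the number of mask voxels.
#' @param maskIndices linear indices of in-mask voxels (ascending), or a 3-D
#'   array mask.
#' @param gridShape integer length-3 grid dimensions.
#' @param path output file path (.nii or .nii.gz).
#' @return invisibly, the path written.
#' @export
saveComponentMaps <- function(maps, maskIndices, gridShape, path) {
  maps <- as.matrix(maps)
  if (is.array(maskIndices) && length(dim(maskIndices)) == 3L)
    maskIndices <- which(maskIndices != 0)
  gridShape <- as.integer(gridShape)
  if (ncol(maps) != length(maskIndices))
    stop(sprintf("maps have %d columns but the mask has %d voxels",
                 ncol(maps), length(maskIndices)))
  if (any(!is.finite(maps))) stop("maps contain non-finite values")
  n <- nrow(maps)
  flat <- matrix(0, prod(gridShape), n)
  flat[maskIndices, ] <- t(maps)
  vol <- array(flat, c(gridShape, n))
  RNifti::writeNifti(vol, path, datatype = "float")
  invisible(path)
}

#' Read component maps saved by [saveComponentMaps()]
#'
#' @param path NIfTI file with maps in the 4th dimension.
#' @param maskIndices linear voxel indices (ascending) or 3-D array mask.
#' @return numeric N x V matrix.
#' @export
loadComponentMaps <- function(path, maskIndices) {
  if (is.array(maskIndices) && length(dim(maskIndices)) == 3L)
    maskIndices <- which(maskIndices != 0)
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  n <- if (length(d) == 3L) 1L else d[4]
  flat <- matrix(as.numeric(vol), prod(d[1:3]), n)
  t(flat[maskIndices, , drop = FALSE])
}

#' Read a clinical covariate table
#'
#' CSV with header \code{subject_id,group,score,duration_months}.
#'
#' @param path CSV file path.
#' @return data.frame with the four columns, \code{group} as character.
#' @export
readClinicalTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "score", "duration_months")
  if (!all(need %in% names(tab)))
    stop("clinical table must have columns subject_id, group, score, duration_months")
  tab[, need]
}
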