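#' Extract ROI-averaged time series from a 4D image and a label atlas
#'
#' Averages, at every frame, the voxels belonging to each atlas region,
#' producing one time series per region. Leading frames can be dropped to
#' discard pre-steady-state volumes (conventionally the first 10 of a
#' 140-frame resting-state acquisition).
#'
#' @param image4d 4D numeric array, frames x X x Y x Z, or a path to a
#'   NIfTI-1 file (read with the RNifti package; NIfTI stores space first,
#'   so a file is interpreted as X x Y x Z x frames and permuted).
#' @param atlas 3D integer array of region labels aligned voxel-for-voxel
#'   with the image's spatial grid (0 = background, regions 1..R), or a
#'   path to a NIfTI-1 label volume.
#' @param dropLeading number of leading frames to drop (default 10 for raw
#'   scans; use 0 for pre-cleaned series).
#' @param framePeriod seconds per frame, stored on the result.
#' @param subjectId,timepoint sample identity stored on the result.
#' @return An [ROITimeSeries-class] with T - dropLeading frames and R columns;
#'   column r at frame t is the arithmetic mean over voxels labelled r of
#'   frame t + dropLeading.
#' @export
#' @examples
#' img <- array(rnorm(5 * 2 * 2 * 1), c(5, 2, 2, 1))
#' atl <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
#' ts <- extractRoiTimeseries(img, atl, dropLeading = 0)
#' dim(seriesValues(ts))
extractRoiTimeseries <- function(image4d, atlas, dropLeading = 10,
                                 framePeriod = 3, subjectId = "unknown",
                                 timepoint = "BL") {
  if (is.character(image4d)) {
    img <- as.array(RNifti::readNifti(image4d))
    if (length(dim(img)) != 4L) stop("image file is not 4D")
    image4d <- aperm(img, c(4L, 1L, 2L, 3L))
  }
  if (is.character(atlas)) {
    atlas <- as.array(RNifti::readNifti(atlas))
    storage.mode(atlas) <- "integer"
  }
  d <- dim(image4d)
  if (length(d) != 4L) stop("image4d must be a 4D array (frames x X x Y x Z)")
  if (!identical(d[-1L], dim(atlas)))
    stop("dimension error: atlas grid ", paste(dim(atlas), collapse = "x"),
         " does not match image spatial grid ", paste(d[-1L], collapse = "x"))
  nT <- d[1L]
  dropLeading <- as.integer(dropLeading)
  if (dropLeading < 0L) stop("dropLeading must be non-negative")
  if (dropLeading >= nT)
    stop("input error: dropLeading (", dropLeading,
         ") must be smaller than the number of frames (", nT, ")")
  labels <- as.integer(atlas)
  R <- max(labels)
  if (R < 1L) stop("atlas error: no labelled regions")
  counts <- tabulate(labels, nbins = R)
  if (any(counts == 0L))
    stop("atlas error: region(s) with zero voxels: ",
         paste(which(counts == 0L), collapse = ", "))
  keep <- (dropLeading + 1L):nT
  # frames x voxels layout: frame index varies fastest in image4d
  mat <- matrix(image4d, nrow = nT)[keep, , drop = FALSE]
  inRegion <- labels > 0L
  # voxel-sum per region via one matrix product, then divide by voxel counts
  sums <- mat[, inRegion, drop = FALSE] %*%
    outer(labels[inRegion], seq_len(R), "==")
  series <- sweep(sums, 2L, counts, "/")
  colnames(series) <- sprintf("ROI%d", seq_len(R))
  roiTimeSeries(series, framePeriod = framePeriod, subjectId = subjectId,
                timepoint = timepoint)
}

#' Pearson functional-connectivity matrix from ROI time series
#'
#' Computes the whole-brain functional-connectivity matrix: entry (i, j) is
#' the Pearson correlation Cov(X_i, X_j) / (sigma_i sigma_j) between the
#' time series of regions i and j, using population (divide-by-T) moments
#' (the shared convention cancels in the ratio). The diagonal is assigned 1
#' rather than computed, and off-diagonal values are clamped to [-1, 1]
#' against floating-point rounding.
#'
#' A zero-variance region cannot carry a correlation; its entries are set
#' to 0 with a warning rather than propagating a division by zero.
#'
#' @param series an [ROITimeSeries-class], or a plain frames x regions matrix.
#' @return An [FCMatrix-class] carrying the input's subject and timepoint.
#' @export
#' @examples
#' ts <- roiTimeSeries(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))
#' fcValues(pearsonFC(ts))
pearsonFC <- function(series) {
  if (is(series, "ROITimeSeries")) {
    x <- series@values
    sid <- series@subjectId
    tp <- series@timepoint
  } else {
    x <- as.matrix(series)
    sid <- "unknown"
    tp <- "BL"
  }
  nT <- nrow(x)
  centered <- sweep(x, 2L, colMeans(x), "-")
  covm <- crossprod(centered) / nT
  sds <- sqrt(diag(covm))
  zeroVar <- sds == 0
  if (any(zeroVar)) {
    warning("zero-variance region(s) ",
            paste(which(zeroVar), collapse = ", "),
            ": their correlation entries are set to 0")
    sds[zeroVar] <- 1  # placeholder; rows/cols zeroed below
  }
  rho <- covm / outer(sds, sds)
  rho[zeroVar, ] <- 0
  rho[, zeroVar] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(x), colnames(x))
  fcMatrix(rho, subjectId = sid, timepoint = tp)
}

#' Framewise-displacement subject exclusion rule
#'
#' Applies the motion quality-control rule: count frames whose framewise
#' displacement (FD, mm) exceeds `fdThreshold`, and exclude the subject if
#' more than `maxBadFrames` such frames occur (at a 3 s TR, 50 frames is
#' 2.5 minutes of data). Both comparisons are strict: FD exactly at the
#' threshold, or exactly `maxBadFrames` bad frames, keeps the subject.
#'
#' @param trace numeric vector of non-negative FD values, one per frame.
#' @param fdThreshold FD threshold in mm (default 0.5).
#' @param maxBadFrames maximum tolerated count of above-threshold frames
#'   (default 50).
#' @return A list with `exclude` (logical), `badFrames` (integer count) and
#'   `nFrames`.
#' @export
#' @examples
#' fdExclude(c(rep(0.6, 51), rep(0, 89)))$exclude
fdExclude <- function(trace, fdThreshold = 0.5, maxBadFrames = 50) {
  trace <- as.numeric(trace)
  if (length(trace) == 0L) stop("input error: empty FD trace")
  if (any(!is.finite(trace)) || any(trace < 0))
    stop("input error: FD values must be finite and non-negative")
  bad <- sum(trace > fdThreshold)
  list(exclude = bad > maxBadFrames, badFrames = as.integer(bad),
       nFrames = length(trace))
}

#' Read and write ROI series, FC matrices, and FD traces as delimited text
#'
#' ROI series and FC matrices are stored as tab-separated text with a
#' one-line header naming ROI columns; FD traces as one value per line.
#'
#' @param path file path.
#' @param object the object to write.
#' @param framePeriod,subjectId,timepoint identity attached on read (the
#'   TSV stores only the numeric table).
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @name connectomeIO
NULL

#' @rdname connectomeIO
#' @export
writeRoiSeries <- function(object, path) {
  utils::write.table(object@values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname connectomeIO
#' @export
readRoiSeries <- function(path, framePeriod = 3, subjectId = "unknown",
                          timepoint = "BL") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  roiTimeSeries(m, framePeriod = framePeriod, subjectId = subjectId,
                timepoint = timepoint)
}

#' @rdname connectomeIO
#' @export
writeFCMatrix <- function(object, path) {
  v <- object@values
  if (is.null(colnames(v))) colnames(v) <- sprintf("ROI%d", seq_len(ncol(v)))
  utils::write.table(v, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname connectomeIO
#' @export
readFCMatrix <- function(path, subjectId = "unknown", timepoint = "BL") {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(m) <- list(colnames(m), colnames(m))
  fcMatrix(m, subjectId = subjectId, timepoint = timepoint)
}

#' @rdname connectomeIO
#' @export
readFDTrace <- function(path) {
  scan(path, what = double(), quiet = TRUE)
}
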