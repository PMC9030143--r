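#' @import methods
NULL

#' Longitudinal scan timepoints
#'
#' The fixed, ordered set of scan timepoints a longitudinal sample carries:
#' baseline, 12 months, and 24 months.
#'
#' @return Character vector `c("BL", "12m", "24m")`.
#' @export
#' @examples
#' timepointLevels()
timepointLevels <- function() c("BL", "12m", "24m")

#' ROITimeSeries: atlas-averaged BOLD signal for one scan
#'
#' Holds the T x R matrix of ROI-averaged signal for a single
#' subject-timepoint scan: T frames (rows) by R atlas regions (columns).
#' This is the input to Pearson functional-connectivity construction.
#'
#' @slot values numeric matrix, T frames x R regions, all finite.
#' @slot framePeriod numeric(1), seconds per frame (the TR).
#' @slot subjectId character(1) opaque subject identifier.
#' @slot timepoint character(1), one of [timepointLevels()].
#'
#' @seealso [roiTimeSeries()], [pearsonFC()], [extractRoiTimeseries()]
#' @export
setClass("ROITimeSeries",
  representation(
    values = "matrix",
    framePeriod = "numeric",
    subjectId = "character",
    timepoint = "character"
  )
)

setValidity("ROITimeSeries", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) < 3L)
    msgs <- c(msgs, "need at least 3 frames (Pearson correlation is degenerate below 3)")
  if (ncol(v) < 2L) msgs <- c(msgs, "need at least 2 regions")
  if (is.numeric(v) && !all(is.finite(v)))
    msgs <- c(msgs, "all signal values must be finite")
  if (length(object@framePeriod) != 1L || !is.finite(object@framePeriod) ||
      object@framePeriod <= 0)
    msgs <- c(msgs, "framePeriod must be a single positive number")
  if (!object@timepoint %in% timepointLevels())
    msgs <- c(msgs, sprintf("timepoint must be one of %s",
                            paste(timepointLevels(), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param values numeric matrix, frames x regions.
#' @param framePeriod seconds per frame (default 3, a typical rs-fMRI TR).
#' @param subjectId subject identifier string.
#' @param timepoint one of [timepointLevels()].
#' @return A [ROITimeSeries-class] object.
#' @export
#' @examples
#' ts <- roiTimeSeries(matrix(rnorm(40), 10, 4), subjectId = "s1")
#' dim(seriesValues(ts))
roiTimeSeries <- function(values, framePeriod = 3, subjectId = "unknown",
                          timepoint = "BL") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ROITimeSeries", values = values, framePeriod = framePeriod,
      subjectId = as.character(subjectId), timepoint = as.character(timepoint))
}

#' FCMatrix: whole-brain functional-connectivity matrix
#'
#' An R x R matrix of pairwise Pearson correlations between ROI time
#' series: symmetric, bounded in [-1, 1], with a unit diagonal that is set
#' (not computed). This is the classifier's per-timepoint input feature.
#'
#' @slot values numeric R x R correlation matrix.
#' @slot subjectId character(1).
#' @slot timepoint character(1), one of [timepointLevels()].
#'
#' @seealso [fcMatrix()], [pearsonFC()], [projectToValidFC()]
#' @export
setClass("FCMatrix",
  representation(
    values = "matrix",
    subjectId = "character",
    timepoint = "character"
  )
)

setValidity("FCMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) < 2L) msgs <- c(msgs, "need at least 2 regions")
  if (!all(is.finite(v))) msgs <- c(msgs, "all entries must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-12)
      msgs <- c(msgs, "matrix must be symmetric to within 1e-12")
    if (!identical(unname(diag(v)), rep(1, nrow(v))) && any(diag(v) != 1))
      msgs <- c(msgs, "diagonal must be exactly 1")
    if (min(v) < -1 || max(v) > 1)
      msgs <- c(msgs, "entries must lie in [-1, 1]")
  }
  if (!object@timepoint %in% timepointLevels())
    msgs <- c(msgs, "timepoint must be one of BL, 12m, 24m")
  if (length(msgs)) msgs else TRUE
})

#' Construct an FCMatrix
#'
#' The input must already satisfy the connectivity-matrix invariants
#' (symmetry, unit diagonal, entries in [-1, 1]); use [projectToValidFC()]
#' to repair an arbitrary square matrix first.
#'
#' @param values numeric R x R matrix.
#' @param subjectId subject identifier string.
#' @param timepoint one of [timepointLevels()].
#' @return An [FCMatrix-class] object.
#' @export
fcMatrix <- function(values, subjectId = "unknown", timepoint = "BL") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("FCMatrix", values = values, subjectId = as.character(subjectId),
      timepoint = as.character(timepoint))
}

#' LongitudinalSample: the unit the CNN+LSTM classifier consumes
#'
#' An ordered triple of FC matrices at (BL, 12m, 24m) for one subject,
#' plus a binary task label (1 = more-diseased class: AD in NC-vs-AD,
#' pMCI in sMCI-vs-pMCI).
#'
#' @slot fcList list of three [FCMatrix-class] objects in timepoint order.
#' @slot label integer(1), 0 or 1.
#' @slot subjectId character(1).
#' @export
setClass("LongitudinalSample",
  representation(
    fcList = "list",
    label = "integer",
    subjectId = "character"
  )
)

setValidity("LongitudinalSample", function(object) {
  msgs <- character()
  if (length(object@fcList) != 3L)
    msgs <- c(msgs, "exactly 3 timepoints (BL, 12m, 24m) are required")
  else {
    if (!all(vapply(object@fcList, is, logical(1), "FCMatrix")))
      msgs <- c(msgs, "fcList entries must be FCMatrix objects")
    else {
      tps <- vapply(object@fcList, function(f) f@timepoint, character(1))
      if (!identical(tps, timepointLevels()))
        msgs <- c(msgs, "fcList must be ordered BL, 12m, 24m")
      rs <- vapply(object@fcList, function(f) nrow(f@values), integer(1))
      if (length(unique(rs)) != 1L)
        msgs <- c(msgs, "all timepoints must share one ROI count")
    }
  }
  if (!object@label %in% c(0L, 1L)) msgs <- c(msgs, "label must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LongitudinalSample
#'
#' @param fcList list of three [FCMatrix-class] objects, ordered BL, 12m, 24m.
#' @param label 0/1 task label (1 = more-diseased class).
#' @param subjectId subject identifier string.
#' @return A [LongitudinalSample-class] object.
#' @export
longitudinalSample <- function(fcList, label, subjectId = "unknown") {
  new("LongitudinalSample", fcList = fcList, label = as.integer(label),
      subjectId = as.character(subjectId))
}

#' CohortSpec: design of a synthetic longitudinal cohort
#'
#' Describes the simulated study: number of atlas regions, frames per scan,
#' per-group subject counts, the magnitude of group-specific connectivity
#' perturbation, its per-timepoint growth for progressive groups (pMCI, AD),
#' the fraction of edges affected, and between-subject correlation jitter.
#'
#' @slot roiCount integer, number of atlas regions R (>= 2).
#' @slot framesPerScan integer, retained frames per scan T (>= 3).
#' @slot groups named integer vector of subject counts; names are a subset
#'   of NC, sMCI, pMCI, AD.
#' @slot edgeEffect numeric >= 0, multiplicative shrinkage toward 0 applied
#'   to affected edges of non-NC groups.
#' @slot progressionRate numeric >= 0, extra shrinkage per timepoint index
#'   for progressive groups (pMCI, AD).
#' @slot affectedEdgeFraction numeric in (0, 1], fraction of the R(R-1)/2
#'   edges perturbed.
#' @slot subjectNoiseSd numeric >= 0, sd of per-subject correlation jitter.
#' @slot trajectoryOnly logical; if TRUE, baseline marginals are identical
#'   across groups and divergence appears only at 12m/24m (the control used
#'   to demonstrate the longitudinal model's value).
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(
    roiCount = "integer",
    framesPerScan = "integer",
    groups = "integer",
    edgeEffect = "numeric",
    progressionRate = "numeric",
    affectedEdgeFraction = "numeric",
    subjectNoiseSd = "numeric",
    trajectoryOnly = "logical",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@roiCount < 2L) msgs <- c(msgs, "roiCount must be >= 2")
  if (object@framesPerScan < 3L) msgs <- c(msgs, "framesPerScan must be >= 3")
  gn <- names(object@groups)
  if (is.null(gn) || !all(gn %in% c("NC", "sMCI", "pMCI", "AD")))
    msgs <- c(msgs, "groups must be named with a subset of NC, sMCI, pMCI, AD")
  if (any(object@groups < 1L)) msgs <- c(msgs, "group counts must be >= 1")
  for (s in c("edgeEffect", "progressionRate", "subjectNoiseSd")) {
    x <- slot(object, s)
    if (length(x) != 1L || !is.finite(x) || x < 0)
      msgs <- c(msgs, paste(s, "must be a single finite non-negative number"))
  }
  f <- object@affectedEdgeFraction
  if (length(f) != 1L || !is.finite(f) || f <= 0 || f > 1)
    msgs <- c(msgs, "affectedEdgeFraction must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults describe the desk-scale study: 20 regions, 130 retained frames
#' (mirroring 140-frame scans minus 10 dropped leading volumes), 50 subjects
#' per group, a moderate connectivity deficit on 30% of edges in disease
#' groups that deepens over the follow-up timepoints for progressive groups.
#'
#' @param roiCount regions R.
#' @param framesPerScan frames T per scan.
#' @param groups named integer vector of per-group subject counts.
#' @param edgeEffect group connectivity-shrinkage magnitude in [0, 1].
#' @param progressionRate extra shrinkage per follow-up timepoint for
#'   progressive groups (pMCI, AD).
#' @param affectedEdgeFraction fraction of edges carrying the group effect.
#' @param subjectNoiseSd sd of per-subject correlation jitter.
#' @param trajectoryOnly make groups identical at baseline, diverging only
#'   at 12m/24m.
#' @param seed RNG seed; the cohort is a pure function of the spec.
#' @return A [CohortSpec-class] object.
#' @export
#' @examples
#' spec <- cohortSpec(groups = c(NC = 5, AD = 5), framesPerScan = 30, seed = 1)
#' spec
cohortSpec <- function(roiCount = 20, framesPerScan = 130,
                       groups = c(NC = 50, sMCI = 50, pMCI = 50, AD = 50),
                       edgeEffect = 0.5, progressionRate = 0.15,
                       affectedEdgeFraction = 0.3, subjectNoiseSd = 0.05,
                       trajectoryOnly = FALSE, seed = 1L) {
  g <- as.integer(groups)
  names(g) <- names(groups)
  new("CohortSpec", roiCount = as.integer(roiCount),
      framesPerScan = as.integer(framesPerScan), groups = g,
      edgeEffect = edgeEffect, progressionRate = progressionRate,
      affectedEdgeFraction = affectedEdgeFraction,
      subjectNoiseSd = subjectNoiseSd,
      trajectoryOnly = isTRUE(trajectoryOnly), seed = as.integer(seed))
}
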