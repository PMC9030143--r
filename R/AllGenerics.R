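#' Accessors for connectivity objects
#'
#' `fcValues()` returns the raw correlation matrix of an [FCMatrix-class];
#' `seriesValues()` the frames x regions signal matrix of an
#' [ROITimeSeries-class]; `roiCount()` the number of atlas regions;
#' `subjectId()` and `timepoint()` the sample identity.
#'
#' @param object an object of one of the package's classes.
#' @return The slot value (matrix, integer, or character as documented).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fcValues", function(object) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("roiCount", function(object) standardGeneric("roiCount"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname accessors
setMethod("fcValues", "FCMatrix", function(object) object@values)
#' @rdname accessors
setMethod("seriesValues", "ROITimeSeries", function(object) object@values)
#' @rdname accessors
setMethod("roiCount", "FCMatrix", function(object) nrow(object@values))
#' @rdname accessors
setMethod("roiCount", "ROITimeSeries", function(object) ncol(object@values))
#' @rdname accessors
setMethod("roiCount", "LongitudinalSample",
          function(object) nrow(object@fcList[[1L]]@values))
#' @rdname accessors
setMethod("subjectId", "FCMatrix", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "ROITimeSeries", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "LongitudinalSample", function(object) object@subjectId)
#' @rdname accessors
setMethod("timepoint", "FCMatrix", function(object) object@timepoint)
#' @rdname accessors
setMethod("timepoint", "ROITimeSeries", function(object) object@timepoint)

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: %d frames x %d regions (TR %.3gs), subject %s, %s\n",
              nrow(object@values), ncol(object@values), object@framePeriod,
              object@subjectId, object@timepoint))
})

setMethod("show", "FCMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("FCMatrix: %d x %d, subject %s, %s; off-diagonal range [%.3f, %.3f]\n",
              nrow(v), ncol(v), object@subjectId, object@timepoint,
              min(off), max(off)))
})

setMethod("show", "LongitudinalSample", function(object) {
  cat(sprintf("LongitudinalSample: subject %s, label %d, %d ROIs, timepoints %s\n",
              object@subjectId, object@label, roiCount(object),
              paste(vapply(object@fcList, timepoint, character(1)),
                    collapse = " -> ")))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: R=%d, T=%d, groups [%s], edgeEffect=%.3g, progressionRate=%.3g,\n  affectedEdgeFraction=%.3g, subjectNoiseSd=%.3g, trajectoryOnly=%s, seed=%d\n",
    object@roiCount, object@framesPerScan,
    paste(sprintf("%s=%d", names(object@groups), object@groups), collapse = ", "),
    object@edgeEffect, object@progressionRate, object@affectedEdgeFraction,
    object@subjectNoiseSd, object@trajectoryOnly, object@seed))
})
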