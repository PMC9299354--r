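#' Accessors for the core classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a cmstrack object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("centerline", function(x) standardGeneric("centerline"))
#' @rdname accessors
#' @export
setMethod("centerline", "TargetPattern", function(x) x@centerline)

#' @rdname accessors
#' @export
setGeneric("boardSize", function(x) standardGeneric("boardSize"))
#' @rdname accessors
#' @export
setMethod("boardSize", "TargetPattern", function(x) x@boardSizeMm)

#' @rdname accessors
#' @export
setGeneric("boardCorners", function(x) standardGeneric("boardCorners"))
#' @rdname accessors
#' @export
setMethod("boardCorners", "TargetPattern", function(x) x@cornersMm)

#' @rdname accessors
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))
#' @rdname accessors
#' @export
setMethod("pathLength", "TargetPattern", function(x) x@pathLengthMm)

#' @rdname accessors
#' @export
setGeneric("lineWidth", function(x) standardGeneric("lineWidth"))
#' @rdname accessors
#' @export
setMethod("lineWidth", "TargetPattern", function(x) x@lineWidthMm)

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setMethod("orientation", "TargetPattern", function(x) x@orientation)

#' @rdname accessors
#' @export
setGeneric("startCorner", function(x) standardGeneric("startCorner"))
#' @rdname accessors
#' @export
setMethod("startCorner", "TargetPattern", function(x) x@startCorner)
#' @rdname accessors
#' @export
setMethod("startCorner", "TrialWindow", function(x) x@startCorner)

#' @rdname accessors
#' @export
setGeneric("rectMatrix", function(x) standardGeneric("rectMatrix"))
#' @rdname accessors
#' @export
setMethod("rectMatrix", "Rectification", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("residualPx", function(x) standardGeneric("residualPx"))
#' @rdname accessors
#' @export
setMethod("residualPx", "Rectification", function(x) x@residualPx)

#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname accessors
#' @export
setMethod("fps", "DotTrack", function(x) x@fps)

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "DotTrack", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))
#' @rdname accessors
#' @export
setMethod("missingFraction", "DotTrack", function(x) x@missingFraction)

#' @rdname accessors
#' @export
setGeneric("trialStart", function(x) standardGeneric("trialStart"))
#' @rdname accessors
#' @export
setMethod("trialStart", "TrialWindow", function(x) x@tStartS)

#' @rdname accessors
#' @export
setGeneric("trialEnd", function(x) standardGeneric("trialEnd"))
#' @rdname accessors
#' @export
setMethod("trialEnd", "TrialWindow", function(x) x@tEndS)

# internal error constructor: classed conditions so callers can test precisely
.err <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cmstrackError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
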