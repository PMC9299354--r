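#' @import methods
NULL

#' TargetPattern: the printed zigzag target in millimetre coordinates
#'
#' Models the physical target of the cervical movement sense test: a thin
#' black zigzag centerline printed on an A3 paper board. All coordinates are
#' in the pattern frame (origin at the top-left board corner, x to the right,
#' y down, units mm).
#'
#' @slot centerline numeric matrix (n x 2), ordered vertices of the zigzag
#'   centerline in mm. The first row is the protocol start vertex.
#' @slot lineWidthMm positive scalar, printed line width (default 1 mm).
#' @slot boardSizeMm numeric length-2, board width and height in mm
#'   (A3 landscape: 420 x 297; portrait: 297 x 420).
#' @slot cornersMm numeric 4 x 2 matrix of board corners in TL, TR, BR, BL
#'   order; these are the rectification fiducials.
#' @slot orientation "horizontal" or "vertical".
#' @slot startCorner protocol start corner, one of "TL", "TR", "BL", "BR".
#' @slot pathLengthMm total centerline length in mm (study target: 1000 mm).
#'
#' @seealso [buildZigzagPattern()]
#' @export
setClass("TargetPattern",
  representation(
    centerline   = "matrix",
    lineWidthMm  = "numeric",
    boardSizeMm  = "numeric",
    cornersMm    = "matrix",
    orientation  = "character",
    startCorner  = "character",
    pathLengthMm = "numeric"
  )
)

.segmentLengths <- function(pts) {
  if (nrow(pts) < 2) return(numeric(0))
  sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
}

setValidity("TargetPattern", function(object) {
  msgs <- character(0)
  cl <- object@centerline
  if (!is.numeric(cl) || ncol(cl) != 2 || nrow(cl) < 2)
    msgs <- c(msgs, "centerline must be a numeric matrix with >= 2 rows and 2 columns")
  if (length(object@boardSizeMm) != 2 || any(object@boardSizeMm <= 0))
    msgs <- c(msgs, "boardSizeMm must be two positive numbers")
  if (length(object@lineWidthMm) != 1 || object@lineWidthMm <= 0)
    msgs <- c(msgs, "lineWidthMm must be a positive scalar")
  if (!identical(dim(object@cornersMm), c(4L, 2L)))
    msgs <- c(msgs, "cornersMm must be a 4 x 2 matrix")
  if (!object@orientation %in% c("horizontal", "vertical"))
    msgs <- c(msgs, "orientation must be 'horizontal' or 'vertical'")
  if (!object@startCorner %in% c("TL", "TR", "BL", "BR"))
    msgs <- c(msgs, "startCorner must be one of TL, TR, BL, BR")
  if (length(msgs) == 0) {
    plen <- sum(.segmentLengths(cl))
    if (abs(plen - object@pathLengthMm) > 1e-6 * max(1, plen))
      msgs <- c(msgs, "pathLengthMm does not equal the summed centerline segment lengths")
    w <- object@boardSizeMm[1]; h <- object@boardSizeMm[2]
    eps <- 1e-9
    if (any(cl[, 1] < -eps | cl[, 1] > w + eps | cl[, 2] < -eps | cl[, 2] > h + eps))
      msgs <- c(msgs, "centerline points must lie inside the board rectangle")
    # convexity / non-degeneracy of the corner quadrilateral
    cc <- object@cornersMm
    cross <- vapply(1:4, function(i) {
      a <- cc[i, ]; b <- cc[i %% 4 + 1, ]; d <- cc[(i + 1) %% 4 + 1, ]
      (b[1] - a[1]) * (d[2] - b[2]) - (b[2] - a[2]) * (d[1] - b[1])
    }, numeric(1))
    if (any(abs(cross) < 1e-9) || !(all(cross > 0) || all(cross < 0)))
      msgs <- c(msgs, "cornersMm must form a non-degenerate convex quadrilateral")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rectification: planar projective transform from pixels to pattern mm
#'
#' Holds the 3 x 3 homography mapping camera pixel coordinates to pattern
#' millimetre coordinates, estimated from the four detected board corners.
#'
#' @slot matrix 3 x 3 invertible homography, pixel -> mm (homogeneous).
#' @slot residualPx maximum reprojection error of the four calibration
#'   corners, in pixels (0 for an exact four-point solve).
#' @slot sourceCornersPx the 4 x 2 pixel corners used, TL, TR, BR, BL order.
#'
#' @seealso [estimateRectification()], [mapToPatternMm()]
#' @export
setClass("Rectification",
  representation(
    matrix          = "matrix",
    residualPx      = "numeric",
    sourceCornersPx = "matrix"
  )
)

setValidity("Rectification", function(object) {
  msgs <- character(0)
  m <- object@matrix
  if (!identical(dim(m), c(3L, 3L))) msgs <- c(msgs, "matrix must be 3 x 3")
  else if (abs(det(m)) < .Machine$double.eps^0.75) msgs <- c(msgs, "matrix must be invertible")
  if (length(object@residualPx) != 1 || object@residualPx < 0)
    msgs <- c(msgs, "residualPx must be a non-negative scalar")
  if (!identical(dim(object@sourceCornersPx), c(4L, 2L)))
    msgs <- c(msgs, "sourceCornersPx must be 4 x 2")
  if (length(msgs)) msgs else TRUE
})

#' DotTrack: a time-stamped laser-dot trajectory in pattern mm
#'
#' One row per video frame at fixed spacing 1/fps. Frames where the dot was
#' not detected carry NA coordinates; gap-filled samples are flagged
#' `interpolated`.
#'
#' @slot fps frames per second (positive).
#' @slot samples data.frame with columns `t_s`, `x_mm`, `y_mm`,
#'   `interpolated` (logical); `t_s` strictly increasing with spacing 1/fps.
#' @slot missingFraction fraction of samples with missing coordinates.
#'
#' @seealso [buildTrajectory()], [fillGaps()]
#' @export
setClass("DotTrack",
  representation(
    fps             = "numeric",
    samples         = "data.frame",
    missingFraction = "numeric"
  )
)

setValidity("DotTrack", function(object) {
  msgs <- character(0)
  if (length(object@fps) != 1 || !is.finite(object@fps) || object@fps <= 0)
    msgs <- c(msgs, "fps must be a positive scalar")
  s <- object@samples
  need <- c("t_s", "x_mm", "y_mm", "interpolated")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, paste("samples must have columns:", paste(need, collapse = ", ")))
  else if (nrow(s) > 1) {
    dt <- diff(s$t_s)
    if (any(dt <= 0) || any(abs(dt - 1 / object@fps) > 1e-6 / object@fps))
      msgs <- c(msgs, "t_s must be strictly increasing with spacing 1/fps")
  }
  if (length(msgs) == 0 && nrow(s) > 0) {
    mf <- mean(is.na(s$x_mm) | is.na(s$y_mm))
    if (abs(mf - object@missingFraction) > 1e-9)
      msgs <- c(msgs, "missingFraction inconsistent with NA sample count")
  }
  if (length(msgs)) msgs else TRUE
})

#' TrialWindow: the start/stop segmentation of one trial
#'
#' @slot tStartS trial start time in seconds.
#' @slot tEndS trial end time in seconds (> tStartS).
#' @slot startCorner,endCorner protocol corner labels for the traced path.
#'
#' @seealso [segmentTrial()], [computeTime()]
#' @export
setClass("TrialWindow",
  representation(
    tStartS     = "numeric",
    tEndS       = "numeric",
    startCorner = "character",
    endCorner   = "character"
  )
)

setValidity("TrialWindow", function(object) {
  if (length(object@tStartS) != 1 || length(object@tEndS) != 1 ||
      !is.finite(object@tStartS) || !is.finite(object@tEndS))
    return("tStartS and tEndS must be finite scalars")
  if (object@tEndS <= object@tStartS) return("tEndS must exceed tStartS")
  TRUE
})

#' @describeIn TargetPattern-class brief display
#' @param object a TargetPattern
#' @export
setMethod("show", "TargetPattern", function(object) {
  cat(sprintf(
    "TargetPattern: %s zigzag, start %s\n  board %g x %g mm, line width %g mm\n  %d vertices, path length %.3f mm\n",
    object@orientation, object@startCorner,
    object@boardSizeMm[1], object@boardSizeMm[2], object@lineWidthMm,
    nrow(object@centerline), object@pathLengthMm))
})

#' @describeIn Rectification-class brief display
#' @param object a Rectification
#' @export
setMethod("show", "Rectification", function(object) {
  cat(sprintf("Rectification: pixel -> mm homography, corner residual %.4g px\n",
              object@residualPx))
})

#' @describeIn DotTrack-class brief display
#' @param object a DotTrack
#' @export
setMethod("show", "DotTrack", function(object) {
  n <- nrow(object@samples)
  cat(sprintf("DotTrack: %d samples @ %g fps (%.2f s), %.1f%% missing\n",
              n, object@fps, if (n) n / object@fps else 0,
              100 * object@missingFraction))
})

#' @describeIn TrialWindow-class brief display
#' @param object a TrialWindow
#' @export
setMethod("show", "TrialWindow", function(object) {
  cat(sprintf("TrialWindow: %.3f -> %.3f s (%s to %s)\n",
              object@tStartS, object@tEndS, object@startCorner, object@endCorner))
})
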