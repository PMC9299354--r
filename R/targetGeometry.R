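# Geometry of the printed zigzag target, corner-fiducial detection, and
# pixel -> mm rectification.

.A3_LANDSCAPE <- c(420, 297)

.boardCornersMm <- function(boardSizeMm) {
  w <- boardSizeMm[1]; h <- boardSizeMm[2]
  matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE,
         dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
}

#' Build the zigzag target pattern
#'
#' Constructs the millimetre-space centerline of the study target: a zigzag
#' line of total length `pathLengthMm` (1000 mm in the clinical protocol)
#' printed on an A3 board. The zigzag has `nPeaks` peaks (2*nPeaks equal
#' length segments alternating between two horizontal levels). Exactly one of
#' the amplitude and the horizontal span is free: with `amplitudeMm = NULL`
#' (default) the zigzag fills the usable board width and the amplitude is
#' solved so the summed segment lengths equal `pathLengthMm`; with a supplied
#' amplitude the horizontal span is solved instead (an amplitude of 0 gives a
#' straight line of length `pathLengthMm`, which needs a board wider than the
#' path).
#'
#' @param orientation "horizontal" or "vertical". The vertical pattern is the
#'   90 degree rotation of the horizontal one about the board center, on the
#'   portrait board.
#' @param startCorner protocol start corner: "TL"/"TR" for horizontal
#'   (left-to-right / right-to-left), "TL"/"BL" for vertical (up-to-down /
#'   down-to-up).
#' @param nPeaks number of zigzag peaks (>= 1); default 5.
#' @param amplitudeMm half the vertical extent of the zigzag in mm, or NULL
#'   to solve it from the path length.
#' @param boardSizeMm board width/height in mm; default A3 landscape
#'   (420 x 297) for horizontal, A3 portrait for vertical.
#' @param pathLengthMm total centerline length in mm; default 1000.
#' @param lineWidthMm printed line width in mm; default 1.
#' @param marginMm margin kept between the pattern and the board edge;
#'   default 10 mm.
#' @return a [TargetPattern-class] object.
#' @examples
#' pat <- buildZigzagPattern()
#' pathLength(pat)   # 1000
#' @export
buildZigzagPattern <- function(orientation = c("horizontal", "vertical"),
                               startCorner = NULL,
                               nPeaks = 5,
                               amplitudeMm = NULL,
                               boardSizeMm = NULL,
                               pathLengthMm = 1000,
                               lineWidthMm = 1,
                               marginMm = 10) {
  orientation <- match.arg(orientation)
  if (is.null(startCorner))
    startCorner <- "TL"
  ok <- if (orientation == "horizontal") c("TL", "TR") else c("TL", "BL")
  if (!startCorner %in% ok)
    .err("invalidInputError",
         sprintf("startCorner must be one of %s for %s orientation",
                 paste(ok, collapse = "/"), orientation))
  if (nPeaks < 1 || nPeaks != round(nPeaks))
    .err("invalidInputError", "nPeaks must be a positive integer")
  if (pathLengthMm <= 0) .err("invalidInputError", "pathLengthMm must be positive")
  if (is.null(boardSizeMm))
    boardSizeMm <- if (orientation == "horizontal") .A3_LANDSCAPE else rev(.A3_LANDSCAPE)
  if (any(boardSizeMm <= 0)) .err("invalidInputError", "boardSizeMm must be positive")

  # build in the landscape frame, rotate afterwards for vertical
  bs <- if (orientation == "horizontal") boardSizeMm else rev(boardSizeMm)
  W <- bs[1]; H <- bs[2]
  nSeg <- 2L * as.integer(nPeaks)
  s <- pathLengthMm / nSeg  # every segment has equal length

  if (is.null(amplitudeMm)) {
    span <- W - 2 * marginMm
    if (span <= 0)
      .err("geometryInfeasibleError", "board too small for the requested margins")
    dx <- span / nSeg
    if (s < dx)
      .err("geometryInfeasibleError",
           "requested path length is shorter than the straight span; cannot fit zigzag")
    A <- sqrt(s^2 - dx^2) / 2
    if (2 * A > H - 2 * marginMm)
      .err("geometryInfeasibleError",
           "solved zigzag amplitude exceeds the usable board height")
  } else {
    if (amplitudeMm < 0) .err("invalidInputError", "amplitudeMm must be >= 0")
    A <- amplitudeMm
    if (2 * A > H - 2 * marginMm)
      .err("geometryInfeasibleError", "amplitude exceeds the usable board height")
    if (s < 2 * A)
      .err("geometryInfeasibleError",
           "segment length implied by path length is shorter than the zigzag rise")
    dx <- sqrt(s^2 - (2 * A)^2)
    span <- nSeg * dx
    if (span > W - 2 * marginMm)
      .err("geometryInfeasibleError",
           "zigzag span exceeds the usable board width; path cannot fit on the board")
  }

  x0 <- (W - span) / 2
  yTop <- H / 2 - A
  yBot <- H / 2 + A
  idx <- 0:nSeg
  pts <- cbind(x = x0 + idx * (span / nSeg),
               y = ifelse(idx %% 2 == 0, yTop, yBot))

  if (orientation == "vertical") {
    # rotate -90 deg about the landscape board center into the portrait frame
    pts <- cbind(x = pts[, 2], y = W - pts[, 1])
    # rotated path runs bottom -> top; protocol "up to down" starts at the top
    if (startCorner == "TL") pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  } else {
    if (startCorner == "TR") pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  }
  colnames(pts) <- c("x", "y")

  new("TargetPattern",
      centerline   = pts,
      lineWidthMm  = lineWidthMm,
      boardSizeMm  = as.numeric(boardSizeMm),
      cornersMm    = .boardCornersMm(boardSizeMm),
      orientation  = orientation,
      startCorner  = startCorner,
      pathLengthMm = sum(.segmentLengths(pts)))
}

# ---- homography ------------------------------------------------------------

# exact four-point planar projective solve (direct linear transform)
.solveHomography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * u, -y * u)
    A[2 * i,     ] <- c(0, 0, 0, x, y, 1, -x * v, -y * v)
    b[2 * i - 1] <- u
    b[2 * i]     <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    .err("degenerateGeometryError",
         "corner configuration is degenerate (collinear or repeated points)"))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

.applyHomography <- function(H, pts) {
  pts <- rbind(t(pts), 1)
  out <- H %*% pts
  w <- out[3, ]
  if (any(abs(w) < 1e-12))
    .err("numericDegeneracyError", "point maps to infinity under the homography")
  cbind(out[1, ] / w, out[2, ] / w)
}

#' Estimate the pixel -> mm rectification from detected board corners
#'
#' Exact four-point planar projective solve mapping the detected pixel
#' corners onto the board's known millimetre corners. With four points the
#' solve is exact, so the corner reprojection residual is zero up to
#' numerical precision; a non-zero residual signals a numerical problem.
#'
#' @param cornersPx 4 x 2 matrix of detected pixel corners in TL, TR, BR, BL
#'   order (see [detectBoardCorners()]).
#' @param pattern the [TargetPattern-class] whose board corners are the
#'   calibration targets.
#' @return a [Rectification-class] object.
#' @export
estimateRectification <- function(cornersPx, pattern) {
  cornersPx <- as.matrix(cornersPx)
  if (!identical(dim(cornersPx), c(4L, 2L)))
    .err("invalidInputError", "cornersPx must be a 4 x 2 matrix")
  cornersMm <- boardCorners(pattern)
  H <- .solveHomography(cornersPx, cornersMm)
  # reprojection residual in pixels: mm corners back through the inverse
  back <- .applyHomography(solve(H), cornersMm)
  res <- max(sqrt(rowSums((back - cornersPx)^2)))
  new("Rectification", matrix = H, residualPx = res,
      sourceCornersPx = cornersPx)
}

#' Map pixel points into pattern millimetre coordinates
#'
#' Homogeneous transform with perspective divide.
#'
#' @param pointPx numeric length-2 point or n x 2 matrix of pixel points.
#' @param rectification a [Rectification-class].
#' @return n x 2 matrix of mm coordinates (a 1 x 2 matrix for a single point).
#' @export
mapToPatternMm <- function(pointPx, rectification) {
  stopifnot(is(rectification, "Rectification"))
  pts <- if (is.null(dim(pointPx))) matrix(pointPx, ncol = 2) else as.matrix(pointPx)
  out <- .applyHomography(rectMatrix(rectification), pts)
  colnames(out) <- c("x_mm", "y_mm")
  out
}

#' Minimum distance from points to the zigzag centerline
#'
#' Euclidean distance from each query point to the nearest point of the
#' centerline polyline (finite segments, not infinite lines). This is the
#' primitive behind the "laser dot on the target line" acuity criterion.
#'
#' @param pointMm numeric length-2 point or n x 2 matrix, pattern mm frame.
#' @param pattern a [TargetPattern-class].
#' @return numeric vector of distances in mm.
#' @export
pointToCenterlineDistance <- function(pointMm, pattern) {
  pts <- if (is.null(dim(pointMm))) matrix(pointMm, ncol = 2) else as.matrix(pointMm)
  cl <- centerline(pattern)
  a <- cl[-nrow(cl), , drop = FALSE]
  b <- cl[-1, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(a))) {
    px <- pts[, 1] - a[i, 1]
    py <- pts[, 2] - a[i, 2]
    tt <- if (len2[i] > 0) pmin(1, pmax(0, (px * d[i, 1] + py * d[i, 2]) / len2[i])) else 0
    dx <- px - tt * d[i, 1]
    dy <- py - tt * d[i, 2]
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

# ---- corner-fiducial detection --------------------------------------------

.quadArea <- function(q) {
  x <- q[, 1]; y <- q[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Detect the four board corner fiducials in a frame
#'
#' The board is the large bright quadrilateral in the scene: the frame is
#' thresholded on luminance, the largest connected bright component is taken
#' as the board, and its four extreme points (min/max of x+y and x-y over
#' component pixel centers) give the corners, returned in fixed
#' TL, TR, BR, BL order (equivalently, ordered by angular position about the
#' component centroid for the in-plane rotations this test produces).
#'
#' Pixel coordinates place the center of image pixel (row r, column c) at
#' (x, y) = (c - 0.5, r - 0.5), origin at the image's top-left corner.
#'
#' @param frame numeric array (height x width x 3), values in 0..1.
#' @param luminanceThreshold board/background luminance split; default 0.5.
#' @param minAreaPx minimum component area in pixels to accept as a board.
#' @param frameIndex optional frame index carried into error conditions.
#' @return list with `cornersPx` (4 x 2 matrix, TL,TR,BR,BL) and
#'   `confidence` in 0..1 (component area over corner-quadrilateral area).
#' @export
detectBoardCorners <- function(frame, luminanceThreshold = 0.5,
                               minAreaPx = 400, frameIndex = NA_integer_) {
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    .err("invalidInputError", "frame must be a height x width x 3 array")
  lum <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  mask <- lum > luminanceThreshold
  if (!any(mask))
    .err("cornerDetectionError", "no bright board region found in frame",
         frameIndex = frameIndex)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  biggest <- which.max(tab)
  if (tab[biggest] < minAreaPx)
    .err("cornerDetectionError",
         "largest bright component is too small to be the board",
         frameIndex = frameIndex)
  idx <- which(lab == biggest, arr.ind = TRUE)
  # frames are stored [row, col, channel]; idx columns are (row, col)
  x <- idx[, 2] - 0.5
  y <- idx[, 1] - 0.5
  s <- x + y; dff <- x - y
  corners <- rbind(
    TL = c(x[which.min(s)],   y[which.min(s)]),
    TR = c(x[which.max(dff)], y[which.max(dff)]),
    BR = c(x[which.max(s)],   y[which.max(s)]),
    BL = c(x[which.min(dff)], y[which.min(dff)]))
  colnames(corners) <- c("x", "y")
  if (nrow(unique(corners)) < 4)
    .err("cornerDetectionError", "fewer than 4 distinct corner candidates",
         frameIndex = frameIndex)
  qa <- .quadArea(corners)
  conf <- if (qa > 0) max(0, min(1, tab[biggest] / qa)) else 0
  list(cornersPx = corners, confidence = conf)
}

#' Median-corner rectification over the leading frames of a trial
#'
#' Camera and board are static within a trial, so the rectification is
#' estimated once from the per-coordinate median of the corner detections in
#' the first `nFrames` frames, which suppresses per-frame jitter.
#'
#' @param frameSource a frame source (see [frameSource()]).
#' @param pattern the [TargetPattern-class] in view.
#' @param nFrames number of leading frames to use; default 30.
#' @param ... passed to [detectBoardCorners()].
#' @return a [Rectification-class].
#' @export
rectificationFromFrames <- function(frameSource, pattern, nFrames = 30, ...) {
  n <- min(nFrames, frameSource$nFrames)
  if (n < 1) .err("invalidInputError", "frame source is empty")
  acc <- array(NA_real_, c(4, 2, n))
  for (i in seq_len(n)) {
    det <- detectBoardCorners(frameSource$getFrame(i), frameIndex = i, ...)
    acc[, , i] <- det$cornersPx
  }
  med <- apply(acc, c(1, 2), stats::median)
  dimnames(med) <- list(c("TL", "TR", "BR", "BL"), c("x", "y"))
  estimateRectification(med, pattern)
}

# ---- pattern spec I/O ------------------------------------------------------

#' Read or write a pattern specification file
#'
#' The pattern spec is a small YAML (or JSON) file with fields
#' `orientation`, `start_corner`, `n_peaks`, `amplitude_mm`, `board_size_mm`,
#' `line_width_mm`, `path_length_mm`; `readPatternSpec` builds the
#' [TargetPattern-class] it describes.
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return `readPatternSpec`: a TargetPattern. `writePatternSpec`: `path`,
#'   invisibly.
#' @export
readPatternSpec <- function(path) {
  if (!file.exists(path)) .err("invalidInputError", paste("no such file:", path))
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  buildZigzagPattern(
    orientation  = spec$orientation %||% "horizontal",
    startCorner  = spec$start_corner %||% "TL",
    nPeaks       = spec$n_peaks %||% 5,
    amplitudeMm  = spec$amplitude_mm,
    boardSizeMm  = spec$board_size_mm,
    pathLengthMm = spec$path_length_mm %||% 1000,
    lineWidthMm  = spec$line_width_mm %||% 1)
}

#' @param pattern a TargetPattern to serialize.
#' @rdname readPatternSpec
#' @export
writePatternSpec <- function(pattern, path) {
  spec <- list(
    orientation    = orientation(pattern),
    start_corner   = startCorner(pattern),
    n_peaks        = (nrow(centerline(pattern)) - 1L) / 2L,
    board_size_mm  = as.numeric(boardSize(pattern)),
    line_width_mm  = lineWidth(pattern),
    path_length_mm = pathLength(pattern))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(spec, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the pattern as a printable SVG
#'
#' Writes a vector drawing of the board outline and the zigzag centerline at
#' true millimetre scale, for physical reproduction of the target.
#'
#' @param pattern a [TargetPattern-class].
#' @param path output .svg path.
#' @return `path`, invisibly.
#' @export
patternToSVG <- function(pattern, path) {
  bs <- boardSize(pattern)
  cl <- centerline(pattern)
  pts <- paste(sprintf("%.3f,%.3f", cl[, 1], cl[, 2]), collapse = " ")
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%gmm" height="%gmm" viewBox="0 0 %g %g">',
            bs[1], bs[2], bs[1], bs[2]),
    sprintf('<rect x="0" y="0" width="%g" height="%g" fill="white" stroke="black" stroke-width="0.5"/>',
            bs[1], bs[2]),
    sprintf('<polyline points="%s" fill="none" stroke="black" stroke-width="%g"/>',
            pts, lineWidth(pattern)),
    '</svg>')
  writeLines(svg, path)
  invisible(path)
}
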