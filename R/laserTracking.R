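# Laser-dot detection, trajectory assembly, gap filling and trial
# segmentation.

#' Frame sources
#'
#' The analysis pipeline consumes frames through a minimal frame-source
#' interface: a list with `nFrames`, `fps` and `getFrame(i)` returning the
#' i-th frame (1-based) as a height x width x 3 numeric array in 0..1.
#' `frameSource()` wraps an arbitrary accessor (e.g. the in-memory renderer),
#' `pngFrameSource()` reads a directory of numbered PNG frames, the format
#' written by [cmdRender()].
#'
#' @param getFrame function(i) returning frame i.
#' @param nFrames number of frames.
#' @param fps frames per second (default 25, the assumed rate for raw image
#'   sequences).
#' @return an object of class `FrameSource`.
#' @export
frameSource <- function(getFrame, nFrames, fps = 25) {
  if (fps <= 0) .err("invalidInputError", "fps must be positive")
  structure(list(getFrame = getFrame, nFrames = as.integer(nFrames), fps = fps),
            class = "FrameSource")
}

#' @param dir directory containing the PNG frames (lexicographic frame order).
#' @rdname frameSource
#' @export
pngFrameSource <- function(dir, fps = 25) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    .err("invalidInputError", paste("no PNG frames found in", dir))
  getFrame <- function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  }
  frameSource(getFrame, length(files), fps)
}

#' Default laser-dot detector configuration
#'
#' @param rednessThreshold minimum redness (R - (G+B)/2) for candidate pixels.
#' @param intensityThreshold minimum red-channel intensity.
#' @param minAreaPx,maxAreaPx connected-component area bounds in px^2.
#' @return a named list of detector parameters.
#' @export
dotDetectorConfig <- function(rednessThreshold = 0.2,
                              intensityThreshold = 0.5,
                              minAreaPx = 3, maxAreaPx = 500) {
  list(rednessThreshold = rednessThreshold,
       intensityThreshold = intensityThreshold,
       minAreaPx = minAreaPx, maxAreaPx = maxAreaPx)
}

# even-odd point-in-polygon test for a handful of query points
.inQuad <- function(x, y, quad) {
  n <- nrow(quad)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- quad[i, 1]; yi <- quad[i, 2]
    xj <- quad[j, 1]; yj <- quad[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Detect the laser dot in one frame
#'
#' The dot is the connected red, high-intensity blob inside the board
#' quadrilateral that maximizes a summed intensity-times-redness score
#' (redness = R - (G+B)/2). The centroid is the score-weighted center of the
#' blob's pixels; the radius is the equivalent circular radius of the blob
#' area. A frame with no blob passing the thresholds and area bounds yields a
#' missing detection (not an error).
#'
#' @param frame height x width x 3 array in 0..1.
#' @param config detector parameters, see [dotDetectorConfig()].
#' @param boardQuadPx optional 4 x 2 pixel quadrilateral; blobs whose
#'   centroid falls outside it are rejected.
#' @param frameIndex frame index recorded in the detection (0-based).
#' @return list with `frameIndex`, `centroidPx` (length-2 or NULL),
#'   `radiusPx` (scalar or NULL) and `confidence` in 0..1 (0 iff missing).
#' @export
detectLaserDot <- function(frame, config = dotDetectorConfig(),
                           boardQuadPx = NULL, frameIndex = 0L) {
  missing <- list(frameIndex = frameIndex, centroidPx = NULL,
                  radiusPx = NULL, confidence = 0)
  if (length(dim(frame)) != 3 || dim(frame)[3] < 3)
    .err("invalidInputError", "frame must be a height x width x 3 array")
  R <- frame[, , 1]; G <- frame[, , 2]; B <- frame[, , 3]
  redness <- R - (G + B) / 2
  mask <- redness > config$rednessThreshold & R > config$intensityThreshold
  if (!any(mask)) return(missing)
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  score <- R * pmax(redness, 0)
  best <- NULL
  bestScore <- -Inf
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < config$minAreaPx || area > config$maxAreaPx) next
    w <- score[idx]
    cx <- sum((idx[, 2] - 0.5) * w) / sum(w)
    cy <- sum((idx[, 1] - 0.5) * w) / sum(w)
    if (!is.null(boardQuadPx) && !.inQuad(cx, cy, boardQuadPx)) next
    s <- sum(w)
    if (s > bestScore) {
      bestScore <- s
      best <- list(centroid = c(cx, cy), area = area,
                   meanRedness = mean(pmax(redness[idx], 0)))
    }
  }
  if (is.null(best)) return(missing)
  list(frameIndex = frameIndex,
       centroidPx = best$centroid,
       radiusPx = sqrt(best$area / pi),
       confidence = max(1e-6, min(1, best$meanRedness)))
}

#' Run dot detection over every frame of a source
#'
#' @param src a [frameSource()].
#' @param config detector parameters.
#' @param boardQuadPx optional board quadrilateral restriction.
#' @return data.frame with columns `frame_index` (0-based), `x_px`, `y_px`,
#'   `radius_px`, `confidence`; missing detections carry NA coordinates.
#' @export
detectDots <- function(src, config = dotDetectorConfig(), boardQuadPx = NULL) {
  n <- src$nFrames
  out <- data.frame(frame_index = seq_len(n) - 1L,
                    x_px = NA_real_, y_px = NA_real_,
                    radius_px = NA_real_, confidence = 0)
  for (i in seq_len(n)) {
    d <- detectLaserDot(src$getFrame(i), config, boardQuadPx, frameIndex = i - 1L)
    if (!is.null(d$centroidPx)) {
      out$x_px[i] <- d$centroidPx[1]
      out$y_px[i] <- d$centroidPx[2]
      out$radius_px[i] <- d$radiusPx
      out$confidence[i] <- d$confidence
    }
  }
  out
}

#' Assemble the millimetre trajectory from per-frame detections
#'
#' Maps each detected centroid through the rectification; sample times are
#' frame_index / fps; frames without a detection are carried as gaps (NA
#' coordinates). The detected dot radius is converted to mm at each sample
#' (local scale of the homography) and kept for the on-line tolerance.
#'
#' @param detections data.frame as returned by [detectDots()] (sorted by
#'   frame_index; a contiguous frame range is assumed and enforced).
#' @param fps frames per second.
#' @param rectification a [Rectification-class].
#' @return a [DotTrack-class].
#' @export
buildTrajectory <- function(detections, fps, rectification) {
  if (fps <= 0) .err("invalidInputError", "fps must be positive")
  fi <- detections$frame_index
  if (is.unsorted(fi, strictly = TRUE))
    .err("invalidInputError", "detections must be sorted by frame_index")
  full <- seq(min(fi), max(fi))
  det <- detections[match(full, fi), ]
  n <- length(full)
  s <- data.frame(t_s = full / fps,
                  x_px = det$x_px, y_px = det$y_px,
                  x_mm = NA_real_, y_mm = NA_real_, r_mm = NA_real_,
                  interpolated = FALSE)
  ok <- which(!is.na(det$x_px))
  if (length(ok)) {
    mm <- mapToPatternMm(cbind(det$x_px[ok], det$y_px[ok]), rectification)
    s$x_mm[ok] <- mm[, 1]
    s$y_mm[ok] <- mm[, 2]
    # local px->mm scale: map a point one radius to the right of the centroid
    edge <- mapToPatternMm(cbind(det$x_px[ok] + det$radius_px[ok], det$y_px[ok]),
                           rectification)
    s$r_mm[ok] <- sqrt(rowSums((edge - mm)^2))
  }
  new("DotTrack", fps = fps, samples = s,
      missingFraction = mean(is.na(s$x_mm)))
}

#' Fill short detection gaps by linear interpolation
#'
#' Internal gaps of at most `maxGapFrames` missing frames are filled by
#' linear interpolation between the flanking detections and flagged
#' `interpolated`; longer gaps (and leading/trailing gaps) are left missing.
#' Non-missing samples are never altered, so the operation is idempotent.
#'
#' @param track a [DotTrack-class].
#' @param maxGapFrames largest gap length (in frames) that is filled.
#' @return a [DotTrack-class] with updated samples and missing fraction.
#' @export
fillGaps <- function(track, maxGapFrames = 5) {
  s <- samples(track)
  miss <- is.na(s$x_mm)
  if (!any(miss) || all(miss)) return(track)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    a <- starts[j] - 1; b <- ends[j] + 1
    if (a < 1 || b > nrow(s)) next          # leading/trailing gap
    if (r$lengths[j] > maxGapFrames) next
    idx <- starts[j]:ends[j]
    w <- (idx - a) / (b - a)
    for (col in c("x_mm", "y_mm", "x_px", "y_px", "r_mm")) {
      if (is.na(s[[col]][a]) || is.na(s[[col]][b])) next
      s[[col]][idx] <- (1 - w) * s[[col]][a] + w * s[[col]][b]
    }
    s$interpolated[idx] <- TRUE
  }
  new("DotTrack", fps = fps(track), samples = s,
      missingFraction = mean(is.na(s$x_mm)))
}

.nearestCornerLabel <- function(point, pattern) {
  cc <- boardCorners(pattern)
  rownames(cc)[which.min(rowSums((cc - matrix(point, 4, 2, byrow = TRUE))^2))]
}

#' Segment the trial window from a trajectory
#'
#' The trial starts when the dot, after dwelling at least `dwellS` seconds
#' within `startRadiusMm` of the pattern's start vertex, first exceeds
#' `velocityOnsetMmS`; it ends when the dot, inside `startRadiusMm` of the
#' end vertex, first drops back below `velocityOnsetMmS` (arrival-and-stop).
#' If the dot enters the end region but never slows, the time of minimum
#' distance to the end vertex is used.
#'
#' @param track a [DotTrack-class] covering the trial.
#' @param pattern the traced [TargetPattern-class].
#' @param dwellS minimum dwell at the start vertex, seconds (default 0.5).
#' @param startRadiusMm radius of the start/end regions, mm (default 15).
#' @param velocityOnsetMmS onset/arrest speed threshold, mm/s (default 10).
#' @return a [TrialWindow-class].
#' @export
segmentTrial <- function(track, pattern, dwellS = 0.5, startRadiusMm = 15,
                         velocityOnsetMmS = 10) {
  s <- samples(track)
  pos <- cbind(s$x_mm, s$y_mm)
  cl <- centerline(pattern)
  sv <- cl[1, ]; ev <- cl[nrow(cl), ]
  dStart <- sqrt((pos[, 1] - sv[1])^2 + (pos[, 2] - sv[2])^2)
  dEnd <- sqrt((pos[, 1] - ev[1])^2 + (pos[, 2] - ev[2])^2)
  n <- nrow(s)
  speed <- c(NA_real_, sqrt(rowSums((pos[-1, , drop = FALSE] -
                                     pos[-n, , drop = FALSE])^2)) * fps(track))
  dwellFrames <- ceiling(dwellS * fps(track))

  inStart <- !is.na(dStart) & dStart <= startRadiusMm
  run <- 0L
  tStartIdx <- NA_integer_
  dwelt <- FALSE
  for (i in seq_len(n)) {
    run <- if (inStart[i]) run + 1L else 0L
    if (run >= dwellFrames) dwelt <- TRUE
    if (dwelt && !is.na(speed[i]) && speed[i] > velocityOnsetMmS) {
      tStartIdx <- i
      break
    }
  }
  if (is.na(tStartIdx))
    .err("unsegmentableTrialError",
         sprintf("no trial onset: dwell>=%.2fs within %.0fmm of start followed by motion not found (min start distance %.1f mm)",
                 dwellS, startRadiusMm, suppressWarnings(min(dStart, na.rm = TRUE))))

  later <- seq(tStartIdx + 1L, length.out = max(0L, n - tStartIdx))
  inEnd <- later[!is.na(dEnd[later]) & dEnd[later] <= startRadiusMm]
  if (length(inEnd) == 0)
    .err("unsegmentableTrialError",
         sprintf("dot never reached within %.0f mm of the end vertex (min end distance %.1f mm)",
                 startRadiusMm, suppressWarnings(min(dEnd[later], na.rm = TRUE))))
  arrested <- inEnd[!is.na(speed[inEnd]) & speed[inEnd] < velocityOnsetMmS]
  tEndIdx <- if (length(arrested)) arrested[1] else inEnd[which.min(dEnd[inEnd])]

  if (s$t_s[tEndIdx] <= s$t_s[tStartIdx])
    .err("unsegmentableTrialError", "degenerate trial window")
  new("TrialWindow",
      tStartS = s$t_s[tStartIdx], tEndS = s$t_s[tEndIdx],
      startCorner = startCorner(pattern),
      endCorner = .nearestCornerLabel(ev, pattern))
}

#' Write / read the trajectory CSV
#'
#' Columns: `frame, t_s, x_px, y_px, x_mm, y_mm, interpolated, on_target`;
#' missing values are written as empty fields. `on_target` is computed from
#' the pattern at `toleranceMm` when a pattern is supplied, otherwise empty.
#'
#' @param track a [DotTrack-class].
#' @param path output CSV path.
#' @param pattern optional [TargetPattern-class] for the `on_target` column.
#' @param toleranceMm on-line tolerance in mm (see [onLineTolerance()]).
#' @return `writeTrajectoryCSV`: `path` invisibly; `readTrajectoryCSV`: a
#'   [DotTrack-class].
#' @export
writeTrajectoryCSV <- function(track, path, pattern = NULL, toleranceMm = NULL) {
  s <- samples(track)
  onTarget <- rep(NA, nrow(s))
  if (!is.null(pattern)) {
    tol <- toleranceMm %||% onLineTolerance(track, pattern)
    ok <- !is.na(s$x_mm)
    onTarget[ok] <- as.integer(
      pointToCenterlineDistance(cbind(s$x_mm[ok], s$y_mm[ok]), pattern) <= tol)
  }
  out <- data.frame(frame = round(s$t_s * fps(track)),
                    t_s = s$t_s, x_px = s$x_px, y_px = s$y_px,
                    x_mm = s$x_mm, y_mm = s$y_mm,
                    interpolated = as.integer(s$interpolated),
                    on_target = onTarget)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @param fps frames per second of the stored track (readTrajectoryCSV).
#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path, fps = NULL) {
  d <- utils::read.csv(path)
  if (is.null(fps)) {
    dt <- diff(d$t_s)
    fps <- 1 / stats::median(dt)
  }
  s <- data.frame(t_s = d$t_s, x_px = d$x_px, y_px = d$y_px,
                  x_mm = d$x_mm, y_mm = d$y_mm, r_mm = NA_real_,
                  interpolated = as.logical(d$interpolated))
  new("DotTrack", fps = fps, samples = s,
      missingFraction = mean(is.na(s$x_mm)))
}
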