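# The four outcome variables of the movement sense test: Acuity, Speed,
# Time, NormAcuity — computed per trial, then pooled per subject.

#' On-line tolerance for the acuity criterion
#'
#' "On the target line" is treated as overlap between the laser dot and the
#' printed line, so the default tolerance on the centroid-to-centerline
#' distance is half the printed line width plus the detected dot radius in
#' mm (median over detected samples). A fixed tolerance can be supplied
#' instead wherever this is used.
#'
#' @param track a [DotTrack-class] (its `r_mm` column supplies the dot
#'   radius; if absent, a 2.5 mm radius typical of a laser dot at 1 m is
#'   assumed).
#' @param pattern the [TargetPattern-class] (supplies the line width).
#' @return tolerance in mm.
#' @export
onLineTolerance <- function(track, pattern) {
  r <- stats::median(samples(track)$r_mm, na.rm = TRUE)
  if (!is.finite(r)) r <- 2.5
  lineWidth(pattern) / 2 + r
}

#' Trial time
#'
#' Seconds to complete the task: the length of the segmented trial window.
#'
#' @param window a [TrialWindow-class].
#' @return time in seconds.
#' @export
computeTime <- function(window) {
  dt <- trialEnd(window) - trialStart(window)
  if (!is.finite(dt) || dt <= 0)
    .err("invalidWindowError", "trial window has non-positive duration")
  dt
}

.windowSamples <- function(track, window) {
  s <- samples(track)
  s[s$t_s >= trialStart(window) & s$t_s <= trialEnd(window), , drop = FALSE]
}

#' Acuity: percentage of trial time on the target line
#'
#' The fraction of in-window samples whose distance to the zigzag centerline
#' is at most `toleranceMm`, as a percentage. Interpolated (gap-filled)
#' samples count; samples still missing after gap filling are excluded from
#' both numerator and denominator.
#'
#' @param track a [DotTrack-class].
#' @param pattern a [TargetPattern-class].
#' @param window a [TrialWindow-class].
#' @param toleranceMm on-line tolerance in mm; default [onLineTolerance()].
#' @return acuity in percent, 0..100.
#' @export
computeAcuity <- function(track, pattern, window, toleranceMm = NULL) {
  if (is.null(toleranceMm)) toleranceMm <- onLineTolerance(track, pattern)
  if (toleranceMm <= 0) .err("invalidInputError", "toleranceMm must be positive")
  s <- .windowSamples(track, window)
  ok <- !is.na(s$x_mm)
  if (sum(ok) == 0)
    .err("uncomputableMetricError", "all samples missing in the trial window")
  d <- pointToCenterlineDistance(cbind(s$x_mm[ok], s$y_mm[ok]), pattern)
  100 * mean(d <= toleranceMm)
}

#' Speed: average movement speed in mm/s
#'
#' Sum of frame-to-frame Euclidean displacements of the non-missing samples
#' in the window, divided by the window duration.
#'
#' @inheritParams computeAcuity
#' @return speed in mm/s.
#' @export
computeSpeed <- function(track, window) {
  s <- .windowSamples(track, window)
  s <- s[!is.na(s$x_mm), , drop = FALSE]
  if (nrow(s) < 2)
    .err("uncomputableMetricError", "fewer than 2 samples in the trial window")
  n <- nrow(s)
  disp <- sqrt((s$x_mm[-1] - s$x_mm[-n])^2 + (s$y_mm[-1] - s$y_mm[-n])^2)
  sum(disp) / computeTime(window)
}

#' Normalized acuity: acuity divided by movement time
#'
#' Accounts for the speed-accuracy trade-off: slower tracing inflates acuity,
#' so acuity is normalized by the time taken. Units %/s (arbitrary units).
#'
#' @param acuityPct acuity in percent.
#' @param timeS trial time in seconds (> 0).
#' @return normalized acuity in arbitrary units.
#' @export
computeNormAcuity <- function(acuityPct, timeS) {
  if (any(timeS <= 0)) .err("invalidInputError", "timeS must be positive")
  acuityPct / timeS
}

#' Score one trial
#'
#' Runs segmentation and the four outcome variables on a trajectory, applying
#' the trial QC rule: a trial fails QC if the missing fraction within the
#' trial window (after gap filling) exceeds `maxMissing`.
#'
#' @param track a gap-filled [DotTrack-class].
#' @param pattern the traced [TargetPattern-class].
#' @param direction protocol direction label ("L-R", "R-L", "U-D", "D-U").
#' @param toleranceMm acuity tolerance; default [onLineTolerance()].
#' @param maxMissing QC bound on the in-window missing fraction (default 0.10).
#' @param ... passed to [segmentTrial()].
#' @return one-row data.frame: `direction`, `acuity_pct`, `speed_mm_s`,
#'   `time_s`, `norm_acuity_au`, `qc_pass`.
#' @export
scoreTrial <- function(track, pattern, direction = "L-R", toleranceMm = NULL,
                       maxMissing = 0.10, ...) {
  window <- segmentTrial(track, pattern, ...)
  timeS <- computeTime(window)
  acuity <- computeAcuity(track, pattern, window, toleranceMm)
  speed <- computeSpeed(track, window)
  sWin <- .windowSamples(track, window)
  qc <- mean(is.na(sWin$x_mm)) <= maxMissing
  data.frame(direction = direction,
             acuity_pct = acuity,
             speed_mm_s = speed,
             time_s = timeS,
             norm_acuity_au = computeNormAcuity(acuity, timeS),
             qc_pass = qc)
}

#' Pool trial results into per-subject outcomes
#'
#' The protocol runs 3 trials in each of 4 directions; direction scores are
#' pooled as the arithmetic mean over all QC-passing trials (with the
#' balanced design this equals the mean of direction means). NormAcuity is
#' pooled from the per-trial values, not recomputed from pooled acuity and
#' time.
#'
#' @param trialResults data.frame of rows from [scoreTrial()].
#' @return one-row data.frame with pooled `acuity_pct`, `speed_mm_s`,
#'   `time_s`, `norm_acuity_au` and `n_trials`.
#' @export
poolTrials <- function(trialResults) {
  ok <- trialResults[trialResults$qc_pass, , drop = FALSE]
  dirs <- unique(trialResults$direction)
  bad <- setdiff(dirs, unique(ok$direction))
  if (length(bad))
    .err("poolingError",
         paste("no QC-passing trials for direction(s):", paste(bad, collapse = ", ")))
  data.frame(acuity_pct = mean(ok$acuity_pct),
             speed_mm_s = mean(ok$speed_mm_s),
             time_s = mean(ok$time_s),
             norm_acuity_au = mean(ok$norm_acuity_au),
             n_trials = nrow(ok))
}
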