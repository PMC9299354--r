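# Ground-truth generators: scripted laser trajectories, rendered video
# frames, and simulated two-occasion three-group cohorts.

#' Scripted laser trajectory
#'
#' Describes a deterministic tracing of the zigzag centerline: a dwell at the
#' start vertex, an arc-length parameterized traverse at the scripted speed
#' profile, and a hold at the end vertex, with optional Gaussian lateral
#' error (optionally AR(1)-correlated to mimic slow head tremor).
#'
#' @param pattern the [TargetPattern-class] to trace.
#' @param durationS traverse duration, seconds.
#' @param dwellS dwell at the start vertex before moving (default 1 s).
#' @param endHoldS hold at the end vertex after arrival (default 1 s).
#' @param speedProfile "constant" or "ramped" (smooth ease-in/ease-out).
#' @param lateralErrorSdMm SD of the lateral (perpendicular) error, mm.
#' @param ar1 AR(1) coefficient of the lateral error in 0..1 (0 = i.i.d.);
#'   the stationary SD stays `lateralErrorSdMm`.
#' @param seed RNG seed for the lateral error.
#' @return object of class `TrajectoryScript`.
#' @export
trajectoryScript <- function(pattern, durationS = 20, dwellS = 1,
                             endHoldS = 1, speedProfile = c("constant", "ramped"),
                             lateralErrorSdMm = 0, ar1 = 0, seed = 1L) {
  speedProfile <- match.arg(speedProfile)
  if (durationS <= 0) .err("invalidInputError", "durationS must be positive")
  if (lateralErrorSdMm < 0 || ar1 < 0 || ar1 >= 1)
    .err("invalidInputError", "need lateralErrorSdMm >= 0 and 0 <= ar1 < 1")
  structure(list(pattern = pattern, durationS = durationS, dwellS = dwellS,
                 endHoldS = endHoldS, speedProfile = speedProfile,
                 lateralErrorSdMm = lateralErrorSdMm, ar1 = ar1,
                 seed = as.integer(seed)),
            class = "TrajectoryScript")
}

# position and unit tangent at arc length s along the polyline
.polylineAt <- function(cl, s) {
  seg <- .segmentLengths(cl)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  frac <- (s - cum[i]) / seg[i]
  a <- cl[i, , drop = FALSE]
  b <- cl[i + 1, , drop = FALSE]
  pos <- a + frac * (b - a)
  tan <- (b - a) / seg[i]
  list(pos = pos, tangent = tan)
}

#' Expected acuity under Gaussian lateral error
#'
#' With i.i.d. Gaussian lateral error of SD sigma and tolerance tau on a
#' straight centerline, the expected fraction of samples on the line is the
#' normal mass within +/- tau: 100 (2 Phi(tau/sigma) - 1); 100 when
#' sigma = 0. Near zigzag vertices the adjacent segment can only shorten the
#' distance, so on a zigzag this is a (tight) lower bound.
#'
#' @param toleranceMm on-line tolerance tau, mm.
#' @param sigmaMm lateral error SD, mm.
#' @return expected acuity in percent.
#' @export
expectedAcuity <- function(toleranceMm, sigmaMm) {
  if (sigmaMm == 0) return(100)
  100 * (2 * stats::pnorm(toleranceMm / sigmaMm) - 1)
}

#' Simulate a scripted trajectory
#'
#' Samples the script at `fps`, adding the lateral error perpendicular to the
#' local path tangent, and returns the millimetre-frame [DotTrack-class]
#' together with the scripted ground truth (time, speed, expected acuity).
#'
#' @param script a [trajectoryScript()].
#' @param fps sampling rate, frames per second (default 25).
#' @param toleranceMm tolerance at which the ground-truth expected acuity is
#'   reported (default 4 mm).
#' @return list with `track` (DotTrack), `groundTruth` (list: `time_s`,
#'   `speed_mm_s`, `expected_acuity_pct`, `tolerance_mm`) and `truePathMm`
#'   (the noise-free positions).
#' @export
simulateTrajectory <- function(script, fps = 25, toleranceMm = 4) {
  pat <- script$pattern
  cl <- centerline(pat)
  L <- pathLength(pat)
  total <- script$dwellS + script$durationS + script$endHoldS
  n <- floor(total * fps) + 1L
  t <- (seq_len(n) - 1L) / fps
  u <- (t - script$dwellS) / script$durationS
  u <- pmin(pmax(u, 0), 1)
  s <- if (script$speedProfile == "constant") L * u
       else L * (3 * u^2 - 2 * u^3)
  pa <- .polylineAt(cl, s)
  pos <- pa$pos
  if (script$lateralErrorSdMm > 0) {
    set.seed(script$seed)
    z <- stats::rnorm(n)
    if (script$ar1 > 0) {
      e <- numeric(n)
      e[1] <- z[1]
      for (i in 2:n) e[i] <- script$ar1 * e[i - 1] + sqrt(1 - script$ar1^2) * z[i]
      z <- e
    }
    off <- script$lateralErrorSdMm * z
    normal <- cbind(-pa$tangent[, 2], pa$tangent[, 1])
    pos <- pos + normal * off
  }
  samp <- data.frame(t_s = t, x_px = NA_real_, y_px = NA_real_,
                     x_mm = pos[, 1], y_mm = pos[, 2], r_mm = NA_real_,
                     interpolated = FALSE)
  track <- new("DotTrack", fps = fps, samples = samp, missingFraction = 0)
  list(track = track,
       groundTruth = list(
         time_s = script$durationS,
         speed_mm_s = L / script$durationS,
         expected_acuity_pct = expectedAcuity(toleranceMm,
                                              script$lateralErrorSdMm),
         tolerance_mm = toleranceMm),
       truePathMm = pa$pos)
}

# ---- camera and renderer ---------------------------------------------------

#' Camera specification for the synthetic renderer
#'
#' A pinhole camera looking at the board center from an oblique pose (the
#' clinic camera sits behind and above the subject's shoulder, so an oblique
#' view is the default). The focal length is solved so the projected board
#' spans `fitFraction` of the image, which keeps the whole board in view.
#'
#' @param imageWidth,imageHeight image size in pixels (default 1280 x 720).
#' @param fps frame rate (default 25).
#' @param distanceMm camera-to-board distance (default 1500 mm).
#' @param pitchDeg,yawDeg oblique viewing angles in degrees (default 20/20).
#' @param rollDeg in-plane camera rotation in degrees (default 0).
#' @param fitFraction fraction of the image the board spans (default 0.8).
#' @param dotRadiusMm rendered laser-dot Gaussian sigma in mm (default 2).
#' @return object of class `CameraSpec`.
#' @export
cameraSpec <- function(imageWidth = 1280, imageHeight = 720, fps = 25,
                       distanceMm = 1500, pitchDeg = 20, yawDeg = 20,
                       rollDeg = 0, fitFraction = 0.8, dotRadiusMm = 2) {
  structure(list(imageWidth = as.integer(imageWidth),
                 imageHeight = as.integer(imageHeight), fps = fps,
                 distanceMm = distanceMm, pitchDeg = pitchDeg,
                 yawDeg = yawDeg, rollDeg = rollDeg,
                 fitFraction = fitFraction, dotRadiusMm = dotRadiusMm),
            class = "CameraSpec")
}

#' Noise specification for the synthetic renderer
#'
#' @param gaussianSd per-pixel Gaussian sensor noise SD (0..1 scale).
#' @param glare optional list of glare blobs, each a list with `x_mm`,
#'   `y_mm` (board position), `sigmaPx`, `amplitude` and `color` (RGB).
#' @param seed RNG seed for the sensor noise.
#' @return object of class `NoiseSpec`.
#' @export
noiseSpec <- function(gaussianSd = 0, glare = list(), seed = 1L) {
  structure(list(gaussianSd = gaussianSd, glare = glare,
                 seed = as.integer(seed)),
            class = "NoiseSpec")
}

# homography mm (board plane) -> px for a CameraSpec viewing `pattern`
.boardHomography <- function(pattern, cam) {
  bs <- boardSize(pattern)
  B <- c(bs[1] / 2, bs[2] / 2, 0)
  p <- cam$pitchDeg * pi / 180
  yw <- cam$yawDeg * pi / 180
  fwd <- c(sin(yw) * cos(p), sin(p), cos(yw) * cos(p))
  fwd <- fwd / sqrt(sum(fwd^2))
  C <- B - cam$distanceMm * fwd
  down <- c(0, 1, 0)
  xc <- c(down[2] * fwd[3] - down[3] * fwd[2],
          down[3] * fwd[1] - down[1] * fwd[3],
          down[1] * fwd[2] - down[2] * fwd[1])
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(fwd[2] * xc[3] - fwd[3] * xc[2],
          fwd[3] * xc[1] - fwd[1] * xc[3],
          fwd[1] * xc[2] - fwd[2] * xc[1])
  if (cam$rollDeg %||% 0 != 0) {
    th <- cam$rollDeg * pi / 180
    xr <- cos(th) * xc + sin(th) * yc
    yc <- -sin(th) * xc + cos(th) * yc
    xc <- xr
  }
  R <- rbind(xc, yc, fwd)
  M <- cbind(R[, 1], R[, 2], -R %*% C)   # (x, y, 1) -> camera coords
  cc <- cbind(boardCorners(pattern), 1)
  pc <- M %*% t(cc)
  u <- pc[1, ] / pc[3, ]
  v <- pc[2, ] / pc[3, ]
  f <- cam$fitFraction * min(cam$imageWidth / diff(range(u)),
                             cam$imageHeight / diff(range(v)))
  cx <- cam$imageWidth / 2 - f * mean(range(u))
  cy <- cam$imageHeight / 2 - f * mean(range(v))
  K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  H <- K %*% M
  px <- .applyHomography(H, boardCorners(pattern))
  m <- 2  # pixels of margin
  if (any(px[, 1] < m | px[, 1] > cam$imageWidth - m |
          px[, 2] < m | px[, 2] > cam$imageHeight - m))
    .err("boardNotInViewError", "projected board does not fit in the image")
  H
}

#' Render a trial as a synthetic frame sequence
#'
#' Produces an in-memory [frameSource()] whose frames show the bright board
#' (its high-contrast corners are the fiducials), the thin black zigzag
#' line, and a red laser dot at the projected track position, with optional
#' sensor noise and glare blobs. The exact projected pixel positions are
#' exported as ground truth.
#'
#' @param pattern the [TargetPattern-class].
#' @param track a millimetre [DotTrack-class] (e.g. from
#'   [simulateTrajectory()]).
#' @param camera a [cameraSpec()].
#' @param noise a [noiseSpec()].
#' @return list with `source` (a FrameSource), `groundTruth` (data.frame:
#'   `frame`, `x_mm`, `y_mm`, `x_px`, `y_px`), `homographyMmToPx`, and
#'   `cornersPx` (true projected board corners).
#' @export
renderFrames <- function(pattern, track, camera = cameraSpec(),
                         noise = noiseSpec()) {
  H <- .boardHomography(pattern, camera)
  s <- samples(track)
  pxPos <- .applyHomography(H, cbind(s$x_mm, s$y_mm))
  w <- camera$imageWidth; h <- camera$imageHeight
  Hinv <- solve(H)

  bgEnv <- new.env()
  makeBackground <- function() {
    # map every pixel center to mm once; classify board / line / outside
    gx <- rep(seq_len(w) - 0.5, each = h)
    gy <- rep(seq_len(h) - 0.5, times = w)
    mm <- .applyHomography(Hinv, cbind(gx, gy))
    bs <- boardSize(pattern)
    inBoard <- mm[, 1] >= 0 & mm[, 1] <= bs[1] & mm[, 2] >= 0 & mm[, 2] <= bs[2]
    lum <- rep(0.15, w * h)
    lum[inBoard] <- 0.95
    onLine <- rep(FALSE, w * h)
    if (any(inBoard)) {
      d <- pointToCenterlineDistance(mm[inBoard, , drop = FALSE], pattern)
      onLine[inBoard] <- d <= lineWidth(pattern) / 2
    }
    lum[onLine] <- 0.05
    bg <- array(lum, c(h, w, 3))
    for (g in noise$glare) {
      gp <- .applyHomography(H, matrix(c(g$x_mm, g$y_mm), 1, 2))
      bg <- .paintBlob(bg, gp[1], gp[2], g$sigmaPx,
                       g$amplitude %||% 1, g$color %||% c(1, 0.75, 0.75))
    }
    bg
  }

  # mean mm/px scale at board center, used to size the dot in pixels
  ctr <- matrix(c(boardSize(pattern) / 2), 1, 2)
  scl <- sqrt(sum((.applyHomography(H, ctr + c(1, 0)) -
                   .applyHomography(H, ctr))^2))
  sigmaPx <- max(1, camera$dotRadiusMm * scl)

  getFrame <- function(i) {
    if (is.null(bgEnv$bg)) bgEnv$bg <- makeBackground()
    fr <- bgEnv$bg
    fr <- .paintBlob(fr, pxPos[i, 1], pxPos[i, 2], sigmaPx, 1, c(1, 0.2, 0.2))
    if (noise$gaussianSd > 0) {
      set.seed(noise$seed + i)
      fr <- fr + array(stats::rnorm(length(fr), sd = noise$gaussianSd), dim(fr))
      fr[fr < 0] <- 0
      fr[fr > 1] <- 1
    }
    fr
  }
  list(source = frameSource(getFrame, nrow(s), camera$fps),
       groundTruth = data.frame(frame = seq_len(nrow(s)) - 1L,
                                x_mm = s$x_mm, y_mm = s$y_mm,
                                x_px = pxPos[, 1], y_px = pxPos[, 2]),
       homographyMmToPx = H,
       cornersPx = .applyHomography(H, boardCorners(pattern)))
}

# alpha-blend a Gaussian blob of the given color into the frame
.paintBlob <- function(fr, cx, cy, sigmaPx, amplitude, color) {
  h <- dim(fr)[1]; w <- dim(fr)[2]
  half <- ceiling(4 * sigmaPx)
  r0 <- max(1, floor(cy + 0.5) - half); r1 <- min(h, floor(cy + 0.5) + half)
  c0 <- max(1, floor(cx + 0.5) - half); c1 <- min(w, floor(cx + 0.5) + half)
  if (r0 > r1 || c0 > c1) return(fr)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 0.5) - cy
  dx <- (cols - 0.5) - cx
  wmat <- amplitude * exp(-(outer(dy^2, dx^2, "+")) / (2 * sigmaPx^2))
  for (ch in 1:3)
    fr[rows, cols, ch] <- fr[rows, cols, ch] * (1 - wmat) + color[ch] * wmat
  fr
}

#' Write a frame source to numbered PNG files
#'
#' @param src a [frameSource()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFramesPNG <- function(src, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(src$nFrames))
    png::writePNG(src$getFrame(i), file.path(dir, sprintf("frame_%06d.png", i)))
  invisible(dir)
}

# ---- cohort simulation -----------------------------------------------------

#' Cohort specification for the psychometric simulator
#'
#' Defaults reproduce the study conditions: group sizes 52/26/28 (controls /
#' idiopathic / traumatic neck pain), group means and between-subject SDs of
#' the four pooled outcomes as observed cross-sectionally, within-subject
#' (occasion) error SDs matching the reported SEMs (SEM equals the
#' within-subject SD under the difference-based definition), a learning
#' shift on occasion 2 for Speed, Time and NormAcuity, and an NDI generating
#' model per patient group correlated with Acuity.
#'
#' @param groups named list (CON, INP, TNP), each with `n`, `mean` and
#'   `betweenSd` (named numeric over the four outcomes).
#' @param withinSd within-subject error SD per outcome.
#' @param occasion2Shift systematic shift added on occasion 2 per outcome.
#' @param ndi per patient group: `mean`, `sd`, and `rWithAcuity`.
#' @return object of class `CohortSpec`.
#' @export
cohortSpec <- function(
    groups = list(
      CON = list(n = 52,
                 mean = c(acuity_pct = 62.7, speed_mm_s = 61.7,
                          time_s = 27.9, norm_acuity_au = 2.7),
                 betweenSd = c(acuity_pct = 11.7, speed_mm_s = 37.4,
                               time_s = 11.5, norm_acuity_au = 0.9)),
      INP = list(n = 26,
                 mean = c(acuity_pct = 64.2, speed_mm_s = 52.5,
                          time_s = 37.2, norm_acuity_au = 2.2),
                 betweenSd = c(acuity_pct = 12.8, speed_mm_s = 32.3,
                               time_s = 20.6, norm_acuity_au = 1.1)),
      TNP = list(n = 28,
                 mean = c(acuity_pct = 66.7, speed_mm_s = 46.0,
                          time_s = 36.5, norm_acuity_au = 2.1),
                 betweenSd = c(acuity_pct = 13.7, speed_mm_s = 22.9,
                               time_s = 13.3, norm_acuity_au = 0.6))),
    withinSd = c(acuity_pct = 4.5, speed_mm_s = 17.3,
                 time_s = 4.4, norm_acuity_au = 0.4),
    occasion2Shift = c(acuity_pct = 0, speed_mm_s = 10,
                       time_s = -3.5, norm_acuity_au = 0.4),
    ndi = list(INP = list(mean = 29.9, sd = 14.0, rWithAcuity = -0.373),
               TNP = list(mean = 40.5, sd = 14.7, rWithAcuity = 0.389))) {
  for (g in groups) {
    if (g$n < 2) .err("invalidInputError", "group sizes must be >= 2")
    if (any(g$betweenSd < 0)) .err("invalidInputError", "SDs must be >= 0")
  }
  if (any(withinSd < 0)) .err("invalidInputError", "withinSd must be >= 0")
  for (m in ndi)
    if (abs(m$rWithAcuity) > 1)
      .err("invalidInputError", "|rWithAcuity| must be <= 1")
  structure(list(groups = groups, withinSd = withinSd,
                 occasion2Shift = occasion2Shift, ndi = ndi),
            class = "CohortSpec")
}

#' Simulate a two-occasion three-group cohort
#'
#' Subject true scores are drawn Normal(group mean, between-subject SD) per
#' outcome; observed scores add independent Normal(0, within-subject SD)
#' occasion error plus the systematic occasion-2 shift. NDI is drawn jointly
#' with the Acuity true score (bivariate normal at the specified
#' correlation) and clipped to 0..100; outcomes are clipped to their
#' physical ranges.
#'
#' @param spec a [cohortSpec()].
#' @param seed RNG seed.
#' @return data.frame with one row per subject x occasion: `subject_id`,
#'   `group`, `occasion`, the four outcomes, `ndi_pct` (NA for controls).
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1L) {
  set.seed(seed)
  vars <- names(spec$withinSd)
  rows <- list()
  sid <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    n <- g$n
    true <- sapply(vars, function(v)
      stats::rnorm(n, g$mean[[v]], g$betweenSd[[v]]))
    true <- matrix(true, nrow = n, dimnames = list(NULL, vars))
    ndi <- rep(NA_real_, n)
    if (gname %in% names(spec$ndi)) {
      m <- spec$ndi[[gname]]
      zAc <- (true[, "acuity_pct"] - g$mean[["acuity_pct"]]) /
        g$betweenSd[["acuity_pct"]]
      ndi <- m$mean + m$sd * (m$rWithAcuity * zAc +
                              sqrt(1 - m$rWithAcuity^2) * stats::rnorm(n))
      ndi <- pmin(100, pmax(0, ndi))
    }
    for (occ in 1:2) {
      obs <- true
      for (v in vars)
        obs[, v] <- obs[, v] + stats::rnorm(n, 0, spec$withinSd[[v]]) +
          if (occ == 2) spec$occasion2Shift[[v]] else 0
      obs[, "acuity_pct"] <- pmin(100, pmax(0.1, obs[, "acuity_pct"]))
      obs[, "speed_mm_s"] <- pmax(0.1, obs[, "speed_mm_s"])
      obs[, "time_s"] <- pmax(0.5, obs[, "time_s"])
      obs[, "norm_acuity_au"] <- pmax(0.01, obs[, "norm_acuity_au"])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%03d", sid + seq_len(n)),
        group = gname, occasion = occ, obs, ndi_pct = ndi,
        row.names = NULL)
    }
    sid <- sid + n
  }
  do.call(rbind, rows)
}

#' Closed-form ICC(2,k) implied by the generating variance components
#'
#' With no occasion shift, ICC(2,k) converges to
#' sigma_b^2 / (sigma_b^2 + sigma_e^2 / k).
#'
#' @param betweenSd between-subject SD.
#' @param withinSd within-subject (occasion error) SD.
#' @param k number of averaged occasions.
#' @return the population ICC.
#' @export
expectedIcc2k <- function(betweenSd, withinSd, k = 2) {
  betweenSd^2 / (betweenSd^2 + withinSd^2 / k)
}
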