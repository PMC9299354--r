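test_that("laser dot is detected within 0.5 px of its rendered position", {
  fx <- smallRender()
  gt <- fx$render$groundTruth
  for (i in c(10, 60, 120)) {
    d <- detectLaserDot(fx$render$source$getFrame(i), frameIndex = i - 1L)
    expect_false(is.null(d$centroidPx))
    expect_lt(sqrt(sum((d$centroidPx - c(gt$x_px[i], gt$y_px[i]))^2)), 0.5)
    expect_gt(d$confidence, 0)
  }
  # a frame with no dot yields a missing detection, not an error
  noDot <- array(0.15, c(90, 160, 3))
  d0 <- detectLaserDot(noDot)
  expect_null(d0$centroidPx)
  expect_null(d0$radiusPx)
  expect_identical(d0$confidence, 0)
})

test_that("the dot beats a glare blob on the intensity-redness score", {
  fx <- smallRender()
  glare <- noiseSpec(glare = list(list(x_mm = 300, y_mm = 80, sigmaPx = 5,
                                       amplitude = 0.9,
                                       color = c(1, 0.75, 0.75))))
  ren <- renderFrames(fx$pattern, fx$sim$track, fx$camera, glare)
  gt <- ren$groundTruth
  d <- detectLaserDot(ren$source$getFrame(60), frameIndex = 59L)
  expect_lt(sqrt(sum((d$centroidPx - c(gt$x_px[60], gt$y_px[60]))^2)), 0.5)
})

test_that("trajectory assembly maps detections to mm and carries gaps", {
  fx <- smallRender()
  rect <- rectificationFromFrames(fx$render$source, fx$pattern, nFrames = 5)
  # 100 synthetic detections at 25 fps: duration spans 3.96 s
  det <- data.frame(frame_index = 0:99,
                    x_px = fx$render$groundTruth$x_px[1:100],
                    y_px = fx$render$groundTruth$y_px[1:100],
                    radius_px = 3, confidence = 1)
  tr <- buildTrajectory(det, 25, rect)
  expect_equal(nrow(samples(tr)), 100L)
  expect_equal(max(samples(tr)$t_s) - min(samples(tr)$t_s), 3.96)
  # ground-truth pixel positions map back to the scripted mm path
  s <- samples(tr)
  errs <- sqrt((s$x_mm - fx$sim$track@samples$x_mm[1:100])^2 +
               (s$y_mm - fx$sim$track@samples$y_mm[1:100])^2)
  expect_lt(max(errs), 0.5)
  # all-missing detections give missing fraction 1
  detNA <- data.frame(frame_index = 0:9, x_px = NA_real_, y_px = NA_real_,
                      radius_px = NA_real_, confidence = 0)
  trNA <- buildTrajectory(detNA, 25, rect)
  expect_equal(missingFraction(trNA), 1)
  expect_error(buildTrajectory(det, 0, rect), class = "invalidInputError")
})

test_that("end-to-end detection reproduces the scripted path within 0.5 mm RMS", {
  fx <- smallRender()
  rect <- rectificationFromFrames(fx$render$source, fx$pattern, nFrames = 5)
  det <- detectDots(fx$render$source)
  tr <- buildTrajectory(det, 25, rect)
  expect_lt(missingFraction(tr), 0.01)
  s <- samples(tr)
  ref <- samples(fx$sim$track)
  ok <- !is.na(s$x_mm)
  rms <- sqrt(mean((s$x_mm[ok] - ref$x_mm[ok])^2 +
                   (s$y_mm[ok] - ref$y_mm[ok])^2))
  expect_lt(rms, 0.5)
})

test_that("gap filling interpolates short gaps only and is idempotent", {
  # straight constant-velocity path: interpolation must land exactly on it
  n <- 40
  s <- data.frame(t_s = (0:(n - 1)) / 25,
                  x_px = NA_real_, y_px = NA_real_,
                  x_mm = seq(0, 39, by = 1), y_mm = seq(0, 78, by = 2),
                  r_mm = 2, interpolated = FALSE)
  full <- new("DotTrack", fps = 25, samples = s, missingFraction = 0)
  expect_equal(samples(fillGaps(full)), samples(full))  # no gaps: identity

  gap2 <- s
  gap2[c(10, 11), c("x_mm", "y_mm")] <- NA
  tr <- new("DotTrack", fps = 25, samples = gap2,
            missingFraction = mean(is.na(gap2$x_mm)))
  filled <- fillGaps(tr, maxGapFrames = 5)
  expect_equal(samples(filled)$x_mm, s$x_mm, tolerance = 1e-12)
  expect_equal(samples(filled)$y_mm, s$y_mm, tolerance = 1e-12)
  expect_true(all(samples(filled)$interpolated[c(10, 11)]))
  expect_equal(missingFraction(filled), 0)
  # non-missing samples never altered; idempotent
  expect_equal(samples(fillGaps(filled)), samples(filled))

  # a gap one frame longer than maxGapFrames is left untouched
  gap3 <- s
  gap3[10:12, c("x_mm", "y_mm")] <- NA
  tr3 <- new("DotTrack", fps = 25, samples = gap3,
             missingFraction = mean(is.na(gap3$x_mm)))
  out3 <- fillGaps(tr3, maxGapFrames = 2)
  expect_true(all(is.na(samples(out3)$x_mm[10:12])))
})

test_that("trial segmentation recovers scripted onset and arrival times", {
  pat <- defaultPattern()
  script <- trajectoryScript(pat, durationS = 20, dwellS = 1, endHoldS = 1)
  sim <- simulateTrajectory(script, fps = 25)
  w <- segmentTrial(sim$track, pat)
  expect_s4_class(w, "TrialWindow")
  expect_lt(abs(trialStart(w) - 1.0), 1.5 / 25)
  expect_lt(abs(trialEnd(w) - 21.0), 1.5 / 25)
  # window length equals the scripted traverse duration within 2 frames
  expect_lt(abs((trialEnd(w) - trialStart(w)) - 20), 2 / 25)
  expect_identical(startCorner(w), "TL")

  # a dot that never leaves the start region cannot be segmented
  s <- samples(sim$track)
  s$x_mm <- s$x_mm[1] + rnorm(nrow(s), 0, 0.01)
  s$y_mm <- s$y_mm[1] + rnorm(nrow(s), 0, 0.01)
  still <- new("DotTrack", fps = 25, samples = s, missingFraction = 0)
  expect_error(segmentTrial(still, pat), class = "unsegmentableTrialError")
})

test_that("trajectory CSV writes the documented columns and round-trips", {
  pat <- defaultPattern()
  sim <- simulateTrajectory(trajectoryScript(pat, durationS = 3), fps = 25)
  f <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(sim$track, f, pat, toleranceMm = 3)
  d <- read.csv(f)
  expect_identical(names(d), c("frame", "t_s", "x_px", "y_px", "x_mm",
                               "y_mm", "interpolated", "on_target"))
  expect_true(all(d$on_target == 1))  # noiseless: always on the line
  tr2 <- readTrajectoryCSV(f)
  expect_equal(fps(tr2), 25, tolerance = 1e-6)
  expect_equal(samples(tr2)$x_mm, samples(sim$track)$x_mm, tolerance = 1e-9)
  unlink(f)
})
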