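# Shared fixtures. Renders are cached so the expensive frame synthesis runs
# once per session.

.fixtureCache <- new.env(parent = emptyenv())

defaultPattern <- function() {
  if (is.null(.fixtureCache$pattern))
    .fixtureCache$pattern <- buildZigzagPattern()
  .fixtureCache$pattern
}

# straight-line degenerate pattern on a wide board (amplitude 0)
straightPattern <- function() {
  if (is.null(.fixtureCache$straight))
    .fixtureCache$straight <- buildZigzagPattern(
      nPeaks = 1, amplitudeMm = 0, boardSizeMm = c(1100, 297),
      pathLengthMm = 1000, marginMm = 20)
  .fixtureCache$straight
}

# a short noiseless rendered trial (4 s traverse at 640x360, 25 fps)
smallRender <- function() {
  if (is.null(.fixtureCache$smallRender)) {
    pat <- defaultPattern()
    script <- trajectoryScript(pat, durationS = 4, dwellS = 1, endHoldS = 1)
    sim <- simulateTrajectory(script, fps = 25)
    cam <- cameraSpec(imageWidth = 640, imageHeight = 360)
    ren <- renderFrames(pat, sim$track, cam)
    .fixtureCache$smallRender <- list(pattern = pat, script = script,
                                      sim = sim, camera = cam, render = ren)
  }
  .fixtureCache$smallRender
}
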