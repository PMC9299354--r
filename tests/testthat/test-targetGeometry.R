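test_that("zigzag pattern geometry solves the requested path length", {
  pat <- buildZigzagPattern()
  expect_s4_class(pat, "TargetPattern")
  expect_lt(abs(pathLength(pat) - 1000), 1e-3)
  seg <- sqrt(rowSums((centerline(pat)[-1, ] - centerline(pat)[-11, ])^2))
  expect_equal(sum(seg), pathLength(pat), tolerance = 1e-9)
  # all vertices inside the board
  cl <- centerline(pat)
  expect_true(all(cl[, 1] >= 0 & cl[, 1] <= 420 & cl[, 2] >= 0 & cl[, 2] <= 297))

  # degenerate zigzag: amplitude 0 on a wide board is a straight line
  straight <- straightPattern()
  expect_lt(abs(pathLength(straight) - 1000), 1e-9)
  expect_equal(length(unique(centerline(straight)[, 2])), 1L)
  expect_equal(max(centerline(straight)[, 1]) - min(centerline(straight)[, 1]),
               1000, tolerance = 1e-9)

  # the same straight line cannot fit on A3
  expect_error(buildZigzagPattern(nPeaks = 1, amplitudeMm = 0,
                                  pathLengthMm = 1000),
               class = "geometryInfeasibleError")
  # path shorter than the span it must cover is infeasible too
  expect_error(buildZigzagPattern(pathLengthMm = 300),
               class = "geometryInfeasibleError")
})

test_that("vertical pattern is the 90-degree rotation of the horizontal one", {
  hor <- buildZigzagPattern("horizontal", startCorner = "TL")
  ver <- buildZigzagPattern("vertical", startCorner = "BL")
  expect_equal(pathLength(ver), pathLength(hor), tolerance = 1e-9)
  # rotate horizontal by -90 deg about the board center into portrait frame
  clh <- centerline(hor)
  bs <- boardSize(hor)
  rot <- cbind(clh[, 2], bs[1] - clh[, 1])
  expect_equal(unname(centerline(ver)), unname(rot), tolerance = 1e-9)
  # start-corner choice only reverses traversal order, never the geometry
  verUD <- buildZigzagPattern("vertical", startCorner = "TL")
  expect_equal(unname(centerline(verUD)),
               unname(centerline(ver)[rev(seq_len(nrow(rot))), ]),
               tolerance = 1e-12)
  expect_equal(pathLength(verUD), pathLength(hor), tolerance = 1e-9)
})

test_that("rectification recovers a known projective warp exactly", {
  pat <- defaultPattern()
  # identity case: pixel corners numerically equal to mm corners
  rect <- estimateRectification(boardCorners(pat), pat)
  H <- rectMatrix(rect) / rectMatrix(rect)[3, 3]
  expect_equal(H, diag(3), tolerance = 1e-9)
  expect_lt(residualPx(rect), 1e-9)

  # known warp: recovered transform maps interior points with < 1e-6 mm error
  W <- matrix(c(1.3, 0.12, 40, -0.08, 1.1, 25, 2e-4, -1e-4, 1), 3, 3,
              byrow = TRUE)
  Winv <- solve(W)  # W maps mm -> px, so recovered rect must equal Winv
  cornersPx <- warpPoints(W, boardCorners(pat))
  rect2 <- estimateRectification(cornersPx, pat)
  set.seed(11)
  mm <- cbind(runif(100, 0, 420), runif(100, 0, 297))
  px <- warpPoints(W, mm)
  back <- mapToPatternMm(px, rect2)
  expect_lt(max(abs(back - mm)), 1e-6)

  # round trip mm -> px -> mm on 1000 random points
  set.seed(12)
  mm <- cbind(runif(1000, 0, 420), runif(1000, 0, 297))
  px <- warpPoints(solve(rectMatrix(rect2)), mm)
  expect_lt(max(sqrt(rowSums((mapToPatternMm(px, rect2) - mm)^2))), 1e-6)

  # collinear corners are degenerate
  bad <- cbind(1:4, 2 * (1:4) + 1)
  expect_error(estimateRectification(bad, pat),
               class = "degenerateGeometryError")
})

test_that("centerline distance matches construction and brute-force oracle", {
  pat <- defaultPattern()
  cl <- centerline(pat)
  # vertex distance is zero
  expect_equal(pointToCenterlineDistance(cl[3, ], pat), 0)
  # a point 3 mm perpendicular from a segment midpoint is at distance 3
  a <- cl[1, ]; b <- cl[2, ]
  mid <- (a + b) / 2
  n <- c(-(b - a)[2], (b - a)[1])
  n <- n / sqrt(sum(n^2))
  expect_equal(pointToCenterlineDistance(mid + 3 * n, pat), 3,
               tolerance = 1e-9)
  # 1000 random queries against the densely resampled oracle
  set.seed(21)
  pts <- cbind(runif(1000, 0, 420), runif(1000, 0, 297))
  expect_lt(max(abs(pointToCenterlineDistance(pts, pat) -
                    bruteforceDistance(pts, pat))), 0.02)
})

test_that("centerline distance is non-negative, zero on the line, 1-Lipschitz", {
  pat <- defaultPattern()
  set.seed(22)
  pts <- cbind(runif(300, -50, 470), runif(300, -50, 350))
  d <- pointToCenterlineDistance(pts, pat)
  expect_true(all(d >= 0))
  # points sampled on the polyline have distance ~0
  cl <- centerline(pat)
  seg <- sample(1:10, 50, replace = TRUE)
  tt <- runif(50)
  on <- cl[seg, ] * (1 - tt) + cl[seg + 1, ] * tt
  expect_lt(max(pointToCenterlineDistance(on, pat)), 1e-9)
  # Lipschitz: |d(p) - d(q)| <= |p - q|
  eps <- cbind(runif(300, -1, 1), runif(300, -1, 1))
  d2 <- pointToCenterlineDistance(pts + eps, pat)
  expect_true(all(abs(d - d2) <= sqrt(rowSums(eps^2)) + 1e-12))
})

test_that("board corners are detected within 2 px on rendered frames", {
  fx <- smallRender()
  det <- detectBoardCorners(fx$render$source$getFrame(1))
  err <- sqrt(rowSums((det$cornersPx - fx$render$cornersPx)^2))
  expect_lt(max(err), 2)
  expect_gte(det$confidence, 0.5)
  expect_equal(rownames(det$cornersPx), c("TL", "TR", "BR", "BL"))

  # blank frame: no board
  blank <- array(0.1, c(90, 160, 3))
  expect_error(detectBoardCorners(blank, frameIndex = 3L),
               class = "cornerDetectionError")

  # in-plane rotation of 5 degrees preserves the TL..BL labelling
  pat <- fx$pattern
  cam <- cameraSpec(imageWidth = 640, imageHeight = 360, rollDeg = 5)
  ren <- renderFrames(pat, fx$sim$track, cam)
  det2 <- detectBoardCorners(ren$source$getFrame(1))
  err2 <- sqrt(rowSums((det2$cornersPx - ren$cornersPx)^2))
  expect_lt(max(err2), 2)
})

test_that("interior mapping error stays below 0.5 mm for noiseless detections", {
  fx <- smallRender()
  set.seed(31)
  mm <- cbind(runif(200, 20, 400), runif(200, 20, 280))
  px <- warpPoints(fx$render$homographyMmToPx, mm)
  # noiseless corners: the exact projected corner coordinates
  rectExact <- estimateRectification(fx$render$cornersPx, fx$pattern)
  backExact <- mapToPatternMm(px, rectExact)
  expect_lt(max(sqrt(rowSums((backExact - mm)^2))), 0.5)
  # thresholded corner detection at 640x360 (~1.2 px/mm): within ~1 px worth
  rectDet <- rectificationFromFrames(fx$render$source, fx$pattern, nFrames = 5)
  backDet <- mapToPatternMm(px, rectDet)
  expect_lt(max(sqrt(rowSums((backDet - mm)^2))), 1.5)
})

test_that("pattern spec files and SVG export round-trip", {
  pat <- buildZigzagPattern(nPeaks = 4, pathLengthMm = 900)
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    writePatternSpec(pat, f)
    pat2 <- readPatternSpec(f)
    expect_equal(centerline(pat2), centerline(pat), tolerance = 1e-9)
    expect_equal(pathLength(pat2), pathLength(pat), tolerance = 1e-9)
    unlink(f)
  }
  svg <- tempfile(fileext = ".svg")
  patternToSVG(pat, svg)
  expect_true(any(grepl("polyline", readLines(svg))))
  unlink(svg)
})
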