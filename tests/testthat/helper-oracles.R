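# Independent oracles used to check the implementation.

# point-to-polyline distance by dense resampling of the centerline
bruteforceDistance <- function(points, pattern, stepMm = 0.01) {
  cl <- centerline(pattern)
  seg <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  dense <- do.call(rbind, lapply(seq_len(nrow(cl) - 1L), function(i) {
    n <- max(2L, ceiling(seg[i] / stepMm) + 1L)
    tt <- seq(0, 1, length.out = n)
    cbind(cl[i, 1] + tt * (cl[i + 1, 1] - cl[i, 1]),
          cl[i, 2] + tt * (cl[i + 1, 2] - cl[i, 2]))
  }))
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  out <- numeric(nrow(pts))
  chunk <- 25L
  for (s in seq(1, nrow(pts), by = chunk)) {
    idx <- s:min(nrow(pts), s + chunk - 1L)
    dx <- outer(pts[idx, 1], dense[, 1], "-")
    dy <- outer(pts[idx, 2], dense[, 2], "-")
    out[idx] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

# AUC by exhaustive case-control pair counting (ties count one half);
# direction "low" means low scores indicate cases
aucPairCount <- function(scores, labels, direction = "low") {
  s <- if (direction == "low") -scores else scores
  cases <- s[labels]
  controls <- s[!labels]
  tot <- 0
  for (a in cases)
    for (b in controls)
      tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# apply a raw 3x3 homography to an n x 2 matrix of points
warpPoints <- function(H, pts) {
  q <- H %*% rbind(t(pts), 1)
  cbind(q[1, ] / q[3, ], q[2, ] / q[3, ])
}
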