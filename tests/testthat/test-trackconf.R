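## exhaustive assignment oracle: all permutations, minimal total cost
bruteAssign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- NULL; bestc <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestc) { bestc <- cc; best <- p }
  }
  list(assign = best, cost = bestc)
}

test_that("the assignment solver matches exhaustive enumeration", {
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(2:6, 1))
    cost <- withr::with_seed(s + 100, matrix(runif(n * n, 0, 50), n, n))
    a <- rodmap:::solveLAP(cost)
    oracle <- bruteAssign(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), oracle$cost,
                 tolerance = 1e-12)
  }
})

test_that("simple trajectories link into single tracks", {
  ## one detection per frame, small displacements: one track of length 10
  det <- data.frame(frame = 0:9, x = (0:9) * 0.5, y = 2)
  tr <- linkTracks(det)
  expect_equal(unique(tr$track_id), 1)
  expect_equal(nrow(tr), 10)
  ## two particles 20 px apart, each moving 1 px/frame: two clean tracks
  det2 <- rbind(data.frame(frame = 0:5, x = 0:5, y = 0, truth = 1),
                data.frame(frame = 0:5, x = 0:5, y = 20, truth = 2))
  tr2 <- linkTracks(det2)
  expect_equal(length(unique(tr2$track_id)), 2)
  ## zero identity switches: each track carries exactly one truth label
  for (id in unique(tr2$track_id))
    expect_equal(length(unique(tr2$truth[tr2$track_id == id])), 1)
  expect_error(linkTracks(det, linkingMaxDist = -1), "must be >= 0")
})

test_that("gap closing bridges a single missed frame", {
  det <- data.frame(frame = c(0, 1, 2, 3, 4, 6, 7, 8),
                    x = c(0, 1, 2, 3, 4, 6, 7, 8), y = 0)
  tr <- linkTracks(det)     # frame 5 missing; gap of 2 frames, 2 px
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 8)
  ## a reappearance beyond the gap distance stays split
  det2 <- data.frame(frame = c(0, 1, 2, 4, 5, 6),
                     x = c(0, 1, 2, 9, 10, 11), y = 0)
  tr2 <- linkTracks(det2)   # jump of 7 px > 4.5 px gate
  expect_equal(length(unique(tr2$track_id)), 2)
  ## a gap longer than maxFrameGap stays split
  det3 <- data.frame(frame = c(0, 1, 2, 6, 7, 8),
                     x = c(0, 1, 2, 3, 4, 5), y = 0)
  tr3 <- linkTracks(det3)
  expect_equal(length(unique(tr3$track_id)), 2)
})

test_that("linking equals globally optimal assignment for small scenes", {
  ## 3 particles, 4 frames, moderate motion: compare stage-1 links per
  ## frame pair against the exhaustive assignment oracle
  set.seed(7)
  base <- cbind(x = c(0, 10, 20), y = c(0, 5, 0))
  det <- do.call(rbind, lapply(0:3, function(f)
    data.frame(frame = f, x = base[, "x"] + rnorm(3, 0, 1),
               y = base[, "y"] + f * 1.5, truth = 1:3)))
  tr <- linkTracks(det)
  expect_equal(length(unique(tr$track_id)), 3)
  for (id in unique(tr$track_id))
    expect_equal(length(unique(tr$truth[tr$track_id == id])), 1)
  ## per-frame-pair optimality against brute force
  for (f in 0:2) {
    a_ <- det[det$frame == f, ]; b_ <- det[det$frame == f + 1, ]
    cost <- outer(a_$x, b_$x, "-")^2 + outer(a_$y, b_$y, "-")^2
    oracle <- bruteAssign(cost)$assign
    got <- rodmap:::gatedAssign(cost, 7.5^2)
    expect_equal(got, oracle)
  }
})

test_that("confinement radius equals its brute-force definition", {
  ## ten identical points: radius 0
  t0 <- data.frame(frame = 0:9, x = 3, y = 4)
  expect_equal(confinementRadius(t0)$radius_px, 0)
  ## alternating (0,0), (2,0): centroid (1,0), all distances 1
  t1 <- data.frame(frame = 0:9, x = rep(c(0, 2), 5), y = 0)
  cr <- confinementRadius(t1)
  expect_equal(cr$radius_px, 1)
  expect_equal(cr$radius_um, 0.06)
  expect_equal(cr$n_used, 10)
  ## 15-point track: only the first ten localizations are used
  set.seed(12)
  t2 <- data.frame(frame = 0:14, x = rnorm(15), y = rnorm(15))
  use <- t2[1:10, ]
  oracle <- mean(sqrt((use$x - mean(use$x))^2 + (use$y - mean(use$y))^2))
  expect_equal(confinementRadius(t2)$radius_px, oracle, tolerance = 1e-14)
  expect_equal(confinementRadius(t2)$n_used, 10)
  expect_error(confinementRadius(data.frame(frame = 0, x = 1, y = 1)),
               "single-localization")
})

test_that("confinement radius is rigid-motion invariant and scales linearly", {
  set.seed(13)
  tr <- data.frame(frame = 0:9, x = rnorm(10), y = rnorm(10))
  r0 <- confinementRadius(tr)$radius_px
  ## translation
  tr2 <- transform(tr, x = x + 5, y = y - 3)
  expect_equal(confinementRadius(tr2)$radius_px, r0, tolerance = 1e-12)
  ## rotation by 37 degrees
  th <- 37 * pi / 180
  tr3 <- data.frame(frame = tr$frame,
                    x = cos(th) * tr$x - sin(th) * tr$y,
                    y = sin(th) * tr$x + cos(th) * tr$y)
  expect_equal(confinementRadius(tr3)$radius_px, r0, tolerance = 1e-12)
  ## linear scaling
  tr4 <- transform(tr, x = 3 * x, y = 3 * y)
  expect_equal(confinementRadius(tr4)$radius_px, 3 * r0, tolerance = 1e-12)
})

test_that("the statistic orders true confinement radii on simulated walks", {
  radii <- c(0.05, 0.1, 0.2, 0.4)
  est <- vapply(seq_along(radii), function(i) {
    w <- simulateConfinedWalk(c(0, 0), radii[i], 0.08, 20, seed = 40 + i)
    confinementRadius(transform(w, x = x / 0.06, y = y / 0.06))$radius_um
  }, 1)
  expect_equal(rank(est), rank(radii))   # rank correlation 1
})

test_that("immobile particles with localization noise match the 2-D normal oracle", {
  ## mean distance from the sample centroid of n=10 iid 2-D normals,
  ## Monte-Carlo oracle
  sloc <- 0.03
  oracle <- withr::with_seed(55, {
    mean(replicate(4000, {
      x <- rnorm(10, 0, sloc); y <- rnorm(10, 0, sloc)
      mean(sqrt((x - mean(x))^2 + (y - mean(y))^2))
    }))
  })
  est <- withr::with_seed(56, {
    mean(replicate(400, {
      tr <- data.frame(frame = 0:9, x = rnorm(10, 5, sloc / 0.06),
                       y = rnorm(10, 5, sloc / 0.06))
      confinementRadius(tr)$radius_um
    }))
  })
  expect_equal(est, oracle, tolerance = 0.05)
})
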