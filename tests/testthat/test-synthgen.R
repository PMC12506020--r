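test_that("spherocylinder masks match analytic geometry", {
  m <- makeCellMask(4, 1, pixelSizeNm = 60, orientationDeg = 0)
  expect_equal(max(EBImage::bwlabel(m)), 1)            # one 4-connected blob
  bbox_r <- diff(range(which(rowSums(m) > 0))) + 1
  bbox_c <- diff(range(which(colSums(m) > 0))) + 1
  expect_equal(bbox_c, 67, tolerance = 1.5 / 67)       # ~ L / px
  expect_equal(bbox_r, 17, tolerance = 1.5 / 17)       # ~ W / px
  ## mask never touches the border
  expect_false(any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
  ## pixel area vs analytic spherocylinder area
  analytic <- 1 * (4 - 1) + pi * 0.5^2
  expect_equal(sum(m) * 0.06^2, analytic, tolerance = 0.02)
  ## degenerate case: length = width is a disk of that diameter
  d <- makeCellMask(1, 1)
  expect_equal(sum(d) * 0.06^2, pi * 0.5^2, tolerance = 0.02)
  expect_error(makeCellMask(1, 2), "lengthUm >= widthUm")
  expect_error(makeCellMask(-1, -2), "lengthUm >= widthUm")
})

test_that("rendered foci have the right peaks, flats, and photon budget", {
  m <- makeCellMask(3, 1)
  quiet <- noiseModel(background = 10, readSigma = 0)
  ## zero foci, zero noise: constant background
  img0 <- renderFoci(m, cbind(x = numeric(0), y = numeric(0)), noise = quiet)
  expect_true(all(img0 == 10))
  ## single focus: global maximum at the true position
  pos <- cbind(x = 25, y = 13)
  img <- renderFoci(m, pos, amplitudes = 500, noise = quiet, seed = 7)
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_lt(sqrt((pk[1, 2] - 1 - 25)^2 + (pk[1, 1] - 1 - 13)^2), 0.5)
  ## integrated signal above background ~ A * 2*pi*sigma^2 (sigma = 2 px)
  expect_equal(sum(img - 10), 500 * 2 * pi * 4, tolerance = 0.01)
  ## determinism under seed
  nm <- noiseModel(background = 10, readSigma = 4)
  expect_identical(renderFoci(m, pos, noise = nm, seed = 3),
                   renderFoci(m, pos, noise = nm, seed = 3))
  expect_error(renderFoci(m, cbind(x = 0, y = 0)), "inside the mask")
})

test_that("confined walks stay confined and equidistribute over the disk", {
  w0 <- simulateConfinedWalk(c(1, 2), 0, 0.1, 50, seed = 1)
  expect_true(all(w0$x == 1 & w0$y == 2))
  ## step >> radius: positions ~ uniform on the disk, mean distance 2R/3
  w <- simulateConfinedWalk(c(0, 0), 0.2, 0.5, 1000, seed = 11)
  d <- sqrt(w$x^2 + w$y^2)
  expect_true(all(d <= 0.2 + 1e-12))
  expect_equal(mean(d), 2 * 0.2 / 3, tolerance = 0.10)
  expect_identical(w, simulateConfinedWalk(c(0, 0), 0.2, 0.5, 1000, seed = 11))
  expect_error(simulateConfinedWalk(c(0, 0), 0.1, 0.1, 5), "nFrames")
})

test_that("nucleoid truth regions hit the requested area fraction and axis", {
  m <- makeCellMask(4, 1)
  expect_identical(renderNucleoid(m, 1, "long", seed = 1)$region, m)
  r <- renderNucleoid(m, 0.5, "short", seed = 2)
  ## area fraction targeted to within one pixel of the requested count
  expect_lte(abs(sum(r$region) - round(0.5 * sum(m))), 1)
  ## extent along the short axis ~ half the cell width (17 px -> ~9)
  idx <- which(r$region, arr.ind = TRUE)
  expect_equal(diff(range(idx[, 1])) + 1, 17 / 2, tolerance = 0.15)
  ## truth is pre-noise: same region under different noise seeds
  r2 <- renderNucleoid(m, 0.5, "short", seed = 99)
  expect_identical(r$region, r2$region)
  expect_error(renderNucleoid(m, 0, "long"), "areaFraction")
  expect_error(renderNucleoid(m, 1.2, "long"), "areaFraction")
})

test_that("protein patterns realize their declared modes", {
  m <- makeCellMask(4, 1)
  quiet <- noiseModel(background = 0, readSigma = 0)
  ## diffuse: constant inside the mask
  img <- renderMcdaPattern(m, "diffuse", noise = quiet)
  expect_equal(length(unique(img[m])), 1)
  ## polar gradient: intensity-weighted centroid flips between halves
  g0 <- renderMcdaPattern(m, "polar_gradient", phase = 0, noise = quiet)
  g5 <- renderMcdaPattern(m, "polar_gradient", phase = 0.5, noise = quiet)
  gx <- coordGridForTest(m)$x
  mid <- mean(range(gx[m]))
  expect_lt(sum(g0 * gx) / sum(g0), mid)
  expect_gt(sum(g5 * gx) / sum(g5), mid)
  expect_error(renderMcdaPattern(m, "banana"), "unknown mode")
})

test_that("correlated channel pairs carry the injected correlation", {
  m <- makeCellMask(25, 2)    # > 1e4 in-mask pixels
  expect_gt(sum(m), 1e4)
  p1 <- renderCorrelatedPair(m, 1, seed = 5)
  expect_equal(cor(p1$imageA[m], p1$imageB[m]), 1, tolerance = 1e-12)
  p0 <- renderCorrelatedPair(m, 0, seed = 6)
  expect_lt(abs(cor(p0$imageA[m], p0$imageB[m])), 0.05)
  p8 <- renderCorrelatedPair(m, 0.8, seed = 7)
  expect_equal(cor(p8$imageA[m], p8$imageB[m]), 0.8, tolerance = 0.03 / 0.8)
  expect_error(renderCorrelatedPair(m, 1.5), "rho")
})

test_that("drift application is exact, channel-uniform, and rejects bad input", {
  sc <- simulateScene(nCells = 2, nFrames = 3, seed = 4)
  st <- sc@stack
  z <- matrix(0L, 3, 2)
  expect_identical(applyDrift(st, z)@pixels, st@pixels)
  dr <- rbind(c(0L, 0L), c(3L, -2L), c(-1L, 4L))
  dst <- applyDrift(st, dr, fill = 0)
  ## every channel of frame 2 shifted identically by (3, -2)
  for (ch in 1:4) {
    orig <- getFrame(st, 2, ch)
    shifted <- getFrame(dst, 2, ch)
    expect_equal(shifted[10 + 3, 10 - 2], orig[10, 10])
  }
  expect_error(applyDrift(st, rbind(c(0, 0), c(0.5, 1), c(0, 0))), "integer")
  expect_error(applyDrift(st, rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L))), "frame 0")
})

test_that("scene ground truth is internally consistent", {
  sc <- simulateScene(nCells = 4, nFrames = 5, fociPerCell = 2,
                      mcdaMode = "polar_gradient", seed = 21)
  ft <- sc@focusTruth
  ## all focus truth positions lie inside their own cell mask
  lbl <- sc@labelTruth
  owner <- lbl[cbind(round(ft$y) + 1, round(ft$x) + 1)]
  expect_true(all(owner == ft$cell_id))
  ## nucleoid truth masks are subsets of the cells
  for (i in 1:4)
    expect_true(all(lbl[sc@nucleoidTruth$masks[[i]]] == i))
  expect_true(all(sc@driftTruth[1, ] == 0))
  ## bit-reproducible
  sc2 <- simulateScene(nCells = 4, nFrames = 5, fociPerCell = 2,
                       mcdaMode = "polar_gradient", seed = 21)
  expect_identical(sc@stack@pixels, sc2@stack@pixels)
  expect_identical(sc@focusTruth, sc2@focusTruth)
})
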