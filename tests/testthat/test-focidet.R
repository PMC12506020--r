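test_that("detector maxima equal the exhaustive LoG oracle", {
  m <- makeCellMask(4, 1)
  img <- renderFoci(m, cbind(x = c(20, 40), y = c(13, 13)), 500,
                    noise = noiseModel(100, 5), seed = 2)
  ## disable pre-filters so both routes see the same image
  p <- fociParams(unsharpAmount = 0, blurSigma = 0)
  det <- detectFoci(img, m, p)
  pre <- img; pre[!m] <- median(img[m])
  resp <- bruteLoG(pre, 3 / (2 * sqrt(2)))
  oracle <- bruteMaxima(resp, 80)
  oracle <- oracle[m[cbind(oracle[, "y"] + 1, oracle[, "x"] + 1)], , drop = FALSE]
  expect_equal(nrow(det), nrow(oracle))
  expect_setequal(paste(det$x, det$y), paste(oracle[, "x"], oracle[, "y"]))
  ## response values agree to numerical precision at the detected positions
  expect_equal(det$quality,
               resp[cbind(det$y + 1, det$x + 1)][order(-det$quality)],
               tolerance = 1e-8)
})

test_that("single and paired foci are localized correctly", {
  m <- makeCellMask(4, 1)
  ## blank cell: nothing detected
  expect_equal(nrow(detectFoci(matrix(50, nrow(m), ncol(m)), m)), 0)
  ## one high-SNR focus within 0.5 px of truth
  img <- renderFoci(m, cbind(x = 33, y = 13), 500,
                    noise = noiseModel(100, 5), seed = 4)
  d <- detectFoci(img, m)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 33)^2 + (d$y - 13)^2), 0.5)
  ## two foci 5 px apart at blob diameter 3: both found
  img2 <- renderFoci(m, cbind(x = c(30, 35), y = c(13, 13)), 500,
                     noise = noiseModel(100, 0), seed = 2)
  d2 <- detectFoci(img2, m)
  expect_equal(nrow(d2), 2)
  expect_setequal(d2$x, c(30, 35))
  expect_error(fociParams(blobDiameterPx = 0), "positive")
  expect_equal(nrow(detectFoci(img, m & FALSE)), 0)
})

test_that("focus intensity integrates the 2r circle on raw pixels", {
  ## uniform image: intensity = lattice points with dx^2 + dy^2 <= (2r)^2
  u <- matrix(1, 21, 21)
  expect_equal(focusIntensity(u, 10, 10, 1.5), 29)
  ## single nonzero pixel at the center
  z <- matrix(0, 15, 15); z[8, 8] <- 7.5
  expect_equal(focusIntensity(z, 7, 7, 1.5), 7.5)
  ## linearity
  m <- makeCellMask(3, 1)
  img <- renderFoci(m, cbind(x = 25, y = 13), 400, noise = quietNoise(10))
  expect_equal(focusIntensity(2 * img, 25, 13, 1.5),
               2 * focusIntensity(img, 25, 13, 1.5))
  ## additivity over disjoint circles and translation invariance
  a <- focusIntensity(img, 10, 10, 1.5) + focusIntensity(img, 40, 13, 1.5)
  sh <- translateForTest(img, 2, 3)
  expect_equal(focusIntensity(sh, 25 + 3, 13 + 2, 1.5),
               focusIntensity(img, 25, 13, 1.5))
  expect_error(focusIntensity(u, 100, 100, 1.5), "outside the image")
})

test_that("focus statistics match brute-force geometry", {
  m <- makeCellMask(4, 1)
  mo <- cellMorphology(CellLabelMap(m * 1L, 60))
  mid <- getMidline(mo, 1)
  det <- data.frame(x = c(20, 30), y = c(13, 13), intensity = c(5, 6))
  img <- matrix(1, nrow(m), ncol(m))
  fs <- focusStats(det, mid, img, m, mo$length_um)
  ## two foci 10 px apart at 60 nm/px
  expect_equal(fs$perFocus$nn_spacing_um, c(0.6, 0.6))
  expect_equal(fs$focus_count, 2)
  expect_equal(fs$whole_cell_intensity_per_length, sum(m) / mo$length_um)
  ## medial distance against a densely-resampled brute-force oracle
  set.seed(31)
  idx <- which(m, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 12), ]
  px <- pick[, 2] - 1; py <- pick[, 1] - 1
  dense <- resampleForTest(mid, 0.1)
  for (i in seq_along(px)) {
    oracle <- min(sqrt((dense[, 1] - px[i])^2 + (dense[, 2] - py[i])^2))
    got <- focusStats(data.frame(x = px[i], y = py[i], intensity = 1),
                      mid, img, m, mo$length_um)$perFocus$medial_distance_um
    expect_equal(got / 0.06, oracle, tolerance = 0.06)
  }
  ## a focus exactly on the midline scores zero
  onmid <- mid[ceiling(nrow(mid) / 2), ]
  fs0 <- focusStats(data.frame(x = onmid[1], y = onmid[2], intensity = 1),
                    mid, img, m, mo$length_um)
  expect_equal(fs0$perFocus$medial_distance_um, 0, tolerance = 1e-12)
  ## single focus: spacing undefined
  expect_true(is.na(fs0$perFocus$nn_spacing_um))
})

test_that("detection recall and precision hold at SNR 10 over many cells", {
  hits <- 0; truth_n <- 0; det_n <- 0
  for (s in 1:25) {
    m <- makeCellMask(3.5, 1)
    dm <- EBImage::distmap(m)
    cand <- which(dm > 4, arr.ind = TRUE)
    pick <- withr::with_seed(s, cand[sample(nrow(cand), 3), ])
    ## enforce spacing >= 2 x blob diameter
    keep <- rep(TRUE, 3)
    d <- as.matrix(dist(pick)); diag(d) <- Inf
    for (i in 2:3) if (any(d[i, seq_len(i - 1)][keep[seq_len(i - 1)]] < 6))
      keep[i] <- FALSE
    pos <- cbind(x = pick[keep, 2] - 1, y = pick[keep, 1] - 1)
    img <- renderFoci(m, pos, 500, noise = noiseModel(100, 50), seed = s)
    det <- detectFoci(img, m)
    truth_n <- truth_n + nrow(pos); det_n <- det_n + nrow(det)
    for (i in seq_len(nrow(pos))) {
      if (nrow(det) && min((det$x - pos[i, 1])^2 + (det$y - pos[i, 2])^2) <= 4)
        hits <- hits + 1
    }
  }
  expect_gte(hits / truth_n, 0.95)    # recall
  expect_gte(hits / det_n, 0.95)      # precision
})
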