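mkCellFixture <- function(lengthUm = 4, widthUm = 1, ori = 0) {
  m <- makeCellMask(lengthUm, widthUm, orientationDeg = ori)
  map <- CellLabelMap(m * 1L, 60)
  mo <- cellMorphology(map)
  list(mask = m, map = map, morph = mo, mid = getMidline(mo, 1),
       w_px = mo$width_um / 0.06)
}

test_that("cell-frame coordinates satisfy their defining geometry", {
  fx <- mkCellFixture()
  arc <- c(0, cumsum(sqrt(rowSums(diff(fx$mid)^2))))
  i <- which.min(abs(arc - arc[length(arc)] / 2))
  cc <- toCellCoords(fx$mid[i, 1], fx$mid[i, 2], fx$mid, fx$w_px)
  expect_equal(cc$region, "cylindrical")
  expect_equal(cc$r_rel, 0, tolerance = 1e-9)
  expect_equal(cc$l_rel, 0.5, tolerance = 0.02)
  ## a point collinear with the end tangent is polar with phi = 0
  tip <- toCellCoords(fx$mid[1, 1] - 3 * sign(fx$mid[2, 1] - fx$mid[1, 1]),
                      fx$mid[1, 2], fx$mid, fx$w_px)
  expect_equal(tip$region, "polar")
  expect_equal(tip$phi, 0, tolerance = 1e-6)
  expect_true(tip$l_rel %in% c(0, 1))
  ## mirror-symmetric points share r_rel and l_rel, opposite sides
  cc2 <- toCellCoords(c(30, 30), c(10, 16), fx$mid, fx$w_px)
  expect_equal(cc2$r_rel[1], cc2$r_rel[2])
  expect_equal(cc2$l_rel[1], cc2$l_rel[2])
  expect_equal(sort(cc2$side), c(-1, 1))
})

test_that("cylindrical coordinates round-trip to within half a pixel", {
  fx <- mkCellFixture(ori = 20)
  idx <- which(fx$mask, arr.ind = TRUE)
  set.seed(9)
  pick <- idx[sample(nrow(idx), 40), ]
  px <- pick[, 2] - 1; py <- pick[, 1] - 1
  cc <- toCellCoords(px, py, fx$mid, fx$w_px)
  ml <- rodmap:::trimMidline(fx$mid, fx$w_px / 2)
  arc <- c(0, cumsum(sqrt(rowSums(diff(ml)^2))))
  cyl <- cc$region == "cylindrical"
  for (k in which(cyl)) {
    s <- cc$l_rel[k] * arc[length(arc)]
    bx <- approx(arc, ml[, 1], s, ties = "ordered")$y
    by <- approx(arc, ml[, 2], s, ties = "ordered")$y
    j <- max(1, min(findInterval(s, arc), nrow(ml) - 1))
    u <- ml[j + 1, ] - ml[j, ]
    u <- u / sqrt(sum(u^2))
    nx <- -u[2] * cc$side[k]; ny <- u[1] * cc$side[k]
    rx <- bx + cc$r_px[k] * nx; ry <- by + cc$r_px[k] * ny
    expect_lt(sqrt((rx - px[k])^2 + (ry - py[k])^2), 0.5)
  }
})

test_that("binning tiles each cell exactly and counts localizations once", {
  fx <- mkCellFixture()
  locs <- data.frame(cell_id = 1, x = 33, y = 13)
  bg <- binLocalizations(locs, fx$map, fx$morph)
  expect_equal(sum(bg$counts), 1)
  expect_equal(sum(bg$counts > 0), 1)        # exactly one bin hit
  ## per-cell bin areas tile the cell area exactly
  expect_equal(sum(bg$areas_um2), sum(fx$mask) * 0.0036)
  expect_equal(bg$overflow, 0)
})

test_that("uniform localizations give area-proportional counts and a flat map", {
  fx <- mkCellFixture()
  idx <- which(fx$mask, arr.ind = TRUE)
  set.seed(17)
  pick <- idx[sample(nrow(idx), 1e4, replace = TRUE), ]
  locs <- data.frame(cell_id = 1, x = pick[, 2] - 1, y = pick[, 1] - 1)
  bg <- binLocalizations(locs, fx$map, fx$morph)
  N <- sum(bg$counts)
  pexp <- colSums(bg$areas_um2) / sum(bg$areas_um2)
  ## multinomial bound: each bin within 4 SD of its expectation
  expect_true(all(abs(colSums(bg$counts) - N * pexp) <=
                    4 * sqrt(N * pexp * (1 - pexp)) + 1))
  ## flat density ~ 1 / cell area (single cell)
  dm <- densityMap(bg, symmetrize = TRUE)
  occ <- dm$table$summed_area_um2 > 0
  expect_equal(median(dm$table$density_per_um2[occ]),
               1 / (sum(fx$mask) * 0.0036), tolerance = 0.1)
})

test_that("density maps conserve mass and are symmetrization-idempotent", {
  sc <- simulateScene(nCells = 4, fociPerCell = 3, seed = 71)
  seg <- segmentCells(getFrame(sc@stack, 1, "phase"))
  mo <- cellMorphology(seg)
  det <- do.call(rbind, lapply(mo$cell_id, function(cid)
    detectFoci(getFrame(sc@stack, 1, "foci"), cellMask(seg, cid),
               cell_id = cid)))
  bg <- binLocalizations(det, seg, mo)
  for (sym in c(TRUE, FALSE)) {
    dm <- densityMap(bg, symmetrize = sym)
    expect_equal(sum(dm$table$density_per_um2 * dm$table$own_area_um2),
                 dm$n_cells, tolerance = 1e-6)
  }
  ## mirrored input: the symmetrized map is unchanged when every
  ## localization is reflected across the (axis-aligned) midline
  fx <- mkCellFixture()
  locs <- data.frame(cell_id = 1, x = c(25, 40, 52), y = c(10, 13, 16))
  mlocs <- transform(locs, y = 26 - y)   # the rod is centered on row 13
  d1 <- densityMap(binLocalizations(locs, fx$map, fx$morph))
  d2 <- densityMap(binLocalizations(mlocs, fx$map, fx$morph))
  expect_equal(d1$table$density_per_um2, d2$table$density_per_um2,
               tolerance = 1e-12)
  ## zero counts: flagged all-zero map
  d0 <- densityMap(binLocalizations(locs[0, ], fx$map, fx$morph))
  expect_true(d0$flagged)
  expect_true(all(d0$table$density_per_um2 == 0))
})

test_that("density maps are equivariant under joint translation", {
  fx <- mkCellFixture()
  locs <- data.frame(cell_id = 1, x = c(25, 40, 52), y = c(10, 13, 16))
  d1 <- densityMap(binLocalizations(locs, fx$map, fx$morph))
  big <- matrix(0L, nrow(fx$mask) + 11, ncol(fx$mask) + 7)
  big[5 + seq_len(nrow(fx$mask)), 3 + seq_len(ncol(fx$mask))] <-
    fx$mask * 1L
  map2 <- CellLabelMap(big, 60)
  mo2 <- cellMorphology(map2)
  locs2 <- transform(locs, x = x + 3, y = y + 5)
  d2 <- densityMap(binLocalizations(locs2, map2, mo2))
  expect_equal(d1$table$density_per_um2, d2$table$density_per_um2,
               tolerance = 1e-6)
})

test_that("mid-cell on-axis localizations concentrate at low r_rel, central l", {
  fx <- mkCellFixture()
  arc <- c(0, cumsum(sqrt(rowSums(diff(fx$mid)^2))))
  i <- which.min(abs(arc - arc[length(arc)] / 2))
  locs <- data.frame(cell_id = 1,
                     x = as.numeric(fx$mid[i, 1]) + rep(c(-1, 0, 1), 4),
                     y = as.numeric(fx$mid[i, 2]))
  dm <- densityMap(binLocalizations(locs, fx$map, fx$morph))
  tab <- dm$table
  hot <- tab[which.max(tab$density_per_um2), ]
  expect_equal(hot$region, "cylindrical")
  expect_equal(hot$ring, 1)                          # innermost ring
  nL <- max(tab$seg[tab$region == "cylindrical"])
  expect_true(hot$seg %in% c(nL / 2, nL / 2 + 1))    # central segments
})

test_that("representative cells reproduce and interpolate their inputs", {
  m <- makeCellMask(3, 1)
  rep1 <- representativeCell(list(m, m, m))
  expect_equal(sum(rep1$mask), sum(m), tolerance = 0.05)
  expect_equal(max(EBImage::bwlabel(rep1$mask)), 1)
  ## two rods of different lengths: representative length in between
  m2 <- makeCellMask(4, 1)
  rep2 <- representativeCell(list(m, m2))
  len <- function(mask) {
    mo <- cellMorphology(CellLabelMap(mask * 1L, 60))
    mo$length_um
  }
  L <- len(rep2$mask)
  expect_gt(L, 2.9); expect_lt(L, 4.1)
  expect_error(representativeCell(list()), "at least one")
})
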