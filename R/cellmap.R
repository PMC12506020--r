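## Normalized cell-frame coordinates and cross-cell localization
## probability-density maps.
##
## Each localization is re-parameterized into (r_rel, l_rel, phi): the
## pole-to-pole midline is trimmed by half a cell width at each end to
## delimit the cylindrical domain; points projecting onto the trimmed
## interior get r (perpendicular distance, normalized by the cell width)
## and l (arc-length fraction), points projecting beyond an end are polar
## and get r (distance to the end) and phi (angle from the outward
## midline tangent). A signed `side` distinguishes the two sides of the
## midline so that fourfold symmetrization (left/right x head/tail) is a
## real fold.

#' Bin layout for cell-frame density maps
#'
#' Defaults: 3 radial rings x 8 longitudinal segments in the cylindrical
#' region and 3 rings x 4 angular sectors in each polar cap, each split by
#' side. The outermost radial edge is open so boundary-pixel quantization
#' cannot fall outside the grid.
#'
#' @param nRings radial rings (cylindrical region).
#' @param nLSegs longitudinal segments over l_rel in [0, 1].
#' @param nPolarRings radial rings in the polar caps.
#' @param nPhiSectors angular sectors over phi in [0, pi/2].
#' @return data.frame of bins with class `binSpec` (attributes carry the
#'   edge vectors).
#' @export
binSpec <- function(nRings = 3L, nLSegs = 8L, nPolarRings = 3L,
                    nPhiSectors = 4L) {
  rEdges <- c(seq(0, 0.5, length.out = nRings + 1)[-(nRings + 1)], Inf)
  lEdges <- seq(0, 1, length.out = nLSegs + 1)
  pEdges <- c(seq(0, 0.5, length.out = nPolarRings + 1)[-(nPolarRings + 1)], Inf)
  phiEdges <- seq(0, pi / 2, length.out = nPhiSectors + 1)
  cyl <- expand.grid(ring = seq_len(nRings), seg = seq_len(nLSegs),
                     side = c(-1L, 1L), cap = NA_integer_,
                     region = "cylindrical", stringsAsFactors = FALSE)
  pol <- expand.grid(ring = seq_len(nPolarRings), seg = seq_len(nPhiSectors),
                     side = c(-1L, 1L), cap = c(0L, 1L),
                     region = "polar", stringsAsFactors = FALSE)
  bins <- rbind(cyl, pol)
  bins$bin_id <- seq_len(nrow(bins))
  structure(bins[, c("bin_id", "region", "ring", "seg", "side", "cap")],
            rEdges = rEdges, lEdges = lEdges, pEdges = pEdges,
            phiEdges = phiEdges, class = c("binSpec", "data.frame"))
}

## trim a pole-to-pole midline by `cut` of arc length at each end; the
## resampled line is re-smoothed so that projection normals vary gently
## between neighboring segments (keeps the coordinate round trip sharp)
trimMidline <- function(midline, cut) {
  samp <- smoothPolyline(resamplePolyline(midline, 0.5), 9L)
  arc <- cumArcLength(samp)
  total <- arc[length(arc)]
  keep <- arc >= cut & arc <= total - cut
  if (sum(keep) < 2) samp[c(1, nrow(samp)), , drop = FALSE] else
    samp[keep, , drop = FALSE]
}

#' Cell-frame coordinates of points
#'
#' @param x,y point coordinates (0-based pixels), inside the cell mask.
#' @param midline pole-to-pole (x, y) polyline from [getMidline()].
#' @param width_px cell width in pixels (normalizes r and sets the trim).
#' @return data.frame: `region` ("cylindrical"/"polar"), `r_px`, `r_rel`,
#'   `l_rel` in [0, 1], `phi` (NA in the cylindrical region), `side`
#'   (-1/+1), `cap` (NA, 0 or 1).
#' @export
toCellCoords <- function(x, y, midline, width_px) {
  ml <- trimMidline(midline, width_px / 2)
  n <- length(x)
  nb <- nrow(ml)
  arc <- cumArcLength(ml)
  total <- arc[length(arc)]
  bestD2 <- rep(Inf, n); bestArc <- numeric(n)
  bestTx <- numeric(n); bestTy <- numeric(n)
  for (i in seq_len(nb - 1)) {
    ax <- ml[i, 1]; ay <- ml[i, 2]
    vx <- ml[i + 1, 1] - ax; vy <- ml[i + 1, 2] - ay
    L2 <- vx^2 + vy^2
    if (L2 == 0) next
    t <- pmin(pmax(((x - ax) * vx + (y - ay) * vy) / L2, 0), 1)
    d2 <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    upd <- d2 < bestD2 - 1e-12
    bestD2[upd] <- d2[upd]
    bestArc[upd] <- arc[i] + t[upd] * sqrt(L2)
    bestTx[upd] <- vx / sqrt(L2); bestTy[upd] <- vy / sqrt(L2)
  }
  r_px <- sqrt(bestD2)
  eps <- 1e-9
  atStart <- bestArc <= eps
  atEnd <- bestArc >= total - eps
  polar <- atStart | atEnd
  ## side: sign of tangent x (point - projection); for polar points the
  ## tangent at the touched end is used, keeping the fold consistent
  relx <- x - (ifelse(polar & atStart, ml[1, 1],
                ifelse(polar & atEnd, ml[nb, 1], 0)))
  ## compute projection point for side in the cylindrical case
  projx <- x; projy <- y
  cyl <- !polar
  ## reconstruct projection from arc position for cylindrical points
  if (any(cyl)) {
    px_ <- approx(arc, ml[, 1], bestArc[cyl], ties = "ordered")$y
    py_ <- approx(arc, ml[, 2], bestArc[cyl], ties = "ordered")$y
    projx[cyl] <- px_; projy[cyl] <- py_
  }
  projx[polar & atStart] <- ml[1, 1]; projy[polar & atStart] <- ml[1, 2]
  projx[polar & atEnd] <- ml[nb, 1]; projy[polar & atEnd] <- ml[nb, 2]
  vx_ <- x - projx; vy_ <- y - projy
  side <- ifelse(bestTx * vy_ - bestTy * vx_ >= 0, 1L, -1L)
  ## polar angle from the outward tangent
  u1 <- c(ml[1, 1] - ml[2, 1], ml[1, 2] - ml[2, 2])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(ml[nb, 1] - ml[nb - 1, 1], ml[nb, 2] - ml[nb - 1, 2])
  u2 <- u2 / sqrt(sum(u2^2))
  phi <- rep(NA_real_, n)
  for (k in which(polar)) {
    u <- if (atStart[k]) u1 else u2
    v <- c(vx_[k], vy_[k])
    nv <- sqrt(sum(v^2))
    phi[k] <- if (nv == 0) 0 else
      min(acos(pmin(pmax(sum(u * v) / nv, -1), 1)), pi / 2)
  }
  data.frame(
    region = ifelse(polar, "polar", "cylindrical"),
    r_px = r_px,
    r_rel = r_px / width_px,
    l_rel = ifelse(atStart, 0, ifelse(atEnd, 1,
                   if (total > 0) bestArc / total else 0.5)),
    phi = phi,
    side = side,
    cap = ifelse(atStart, 0L, ifelse(atEnd, 1L, NA_integer_)))
}

## map cell-frame coordinates to bin ids of a binSpec (half-open bins,
## boundary values to the lower-index bin; the last edge is closed)
coordsToBin <- function(cc, spec) {
  rE <- attr(spec, "rEdges"); lE <- attr(spec, "lEdges")
  pE <- attr(spec, "pEdges"); phiE <- attr(spec, "phiEdges")
  key <- function(region, ring, seg, side, cap) {
    paste(region, ring, seg, side, ifelse(is.na(cap), "NA", cap))
  }
  lut <- setNames(spec$bin_id,
                  key(spec$region, spec$ring, spec$seg, spec$side, spec$cap))
  isC <- cc$region == "cylindrical"
  ring <- integer(nrow(cc)); seg <- integer(nrow(cc))
  ring[isC] <- findInterval(cc$r_rel[isC], rE, rightmost.closed = TRUE)
  seg[isC] <- pmin(findInterval(cc$l_rel[isC], lE, rightmost.closed = TRUE),
                   length(lE) - 1)
  ring[!isC] <- findInterval(cc$r_rel[!isC], pE, rightmost.closed = TRUE)
  seg[!isC] <- pmin(findInterval(cc$phi[!isC], phiE, rightmost.closed = TRUE),
                    length(phiE) - 1)
  ## l_rel = 0 in the cylindrical region maps to the first segment
  seg[seg == 0] <- 1L
  ring[ring == 0] <- 1L
  unname(lut[key(cc$region, ring, seg, cc$side, cc$cap)])
}

#' Bin localizations into the cell-frame grid, with per-cell bin areas
#'
#' Counts each localization in its (r_rel, l_rel, phi) bin and computes the
#' per-cell area of every bin by classifying every cell-mask pixel and
#' summing pixel areas, so that per cell the bin areas tile the cell
#' exactly.
#'
#' @param localizations data.frame with `cell_id`, `x`, `y` (pixels).
#' @param map a [CellLabelMap-class].
#' @param morphology result of [cellMorphology()] on `map`.
#' @param spec a [binSpec()].
#' @return list of class `binGrid`: `spec`, `counts` and `areas_um2`
#'   (cells x bins matrices), `cell_ids`, `overflow` (localizations whose
#'   host cell has no morphology).
#' @export
binLocalizations <- function(localizations, map, morphology,
                             spec = binSpec()) {
  px_um <- pixelSizeNm(map) / 1000
  ids <- morphology$cell_id
  counts <- matrix(0L, length(ids), nrow(spec),
                   dimnames = list(ids, spec$bin_id))
  areas <- matrix(0, length(ids), nrow(spec),
                  dimnames = list(ids, spec$bin_id))
  overflow <- 0L
  for (j in seq_along(ids)) {
    cid <- ids[j]
    m <- cellMask(map, cid)
    mid <- getMidline(morphology, cid)
    w_px <- morphology$width_um[j] / px_um
    ## per-cell bin areas from every mask pixel
    idx <- which(m, arr.ind = TRUE)
    ccA <- toCellCoords(idx[, 2] - 1, idx[, 1] - 1, mid, w_px)
    binA <- coordsToBin(ccA, spec)
    tb <- table(factor(binA, levels = spec$bin_id))
    areas[j, ] <- as.numeric(tb) * px_um^2
    loc <- localizations[localizations$cell_id == cid, , drop = FALSE]
    if (nrow(loc)) {
      ccL <- toCellCoords(loc$x, loc$y, mid, w_px)
      binL <- coordsToBin(ccL, spec)
      tbL <- table(factor(binL, levels = spec$bin_id))
      counts[j, ] <- as.integer(tbL)
      overflow <- overflow + sum(is.na(binL))
    }
  }
  overflow <- overflow +
    sum(!(localizations$cell_id %in% ids))
  structure(list(spec = spec, counts = counts, areas_um2 = areas,
                 cell_ids = ids, overflow = overflow), class = "binGrid")
}

## fourfold equivalence class of each bin: sides folded together and, in
## the cylindrical region, l folded about 1/2; polar caps folded together
symmetryClasses <- function(spec) {
  nL <- max(spec$seg[spec$region == "cylindrical"])
  segSym <- ifelse(spec$region == "cylindrical",
                   pmin(spec$seg, nL + 1L - spec$seg), spec$seg)
  paste(spec$region, spec$ring, segSym)
}

#' Aggregate a bin grid into a probability-density map
#'
#' Counts and areas are summed across cells; under fourfold symmetrization
#' they are additionally summed across the four symmetric equivalents of
#' each bin (left/right of the midline x head/tail of the cell). The
#' density of a bin is `(summed counts / summed area) / total counts x
#' n_cells`, in um^-2, so that `sum(density x area) = n_cells`.
#'
#' @param binGrid result of [binLocalizations()].
#' @param symmetrize fold the four symmetric equivalents (default TRUE).
#' @return list of class `densityMap`: `table` (per-bin data.frame with
#'   summed counts, areas, densities and the symmetry class), `n_cells`,
#'   `total_counts`, `symmetrized`, `flagged` (zero total counts).
#' @export
densityMap <- function(binGrid, symmetrize = TRUE) {
  spec <- binGrid$spec
  C <- colSums(binGrid$counts)
  A <- colSums(binGrid$areas_um2)
  ncell <- length(binGrid$cell_ids)
  totC <- sum(C)
  cls <- if (symmetrize) symmetryClasses(spec) else as.character(spec$bin_id)
  Csum <- tapply(C, cls, sum)[cls]
  Asum <- tapply(A, cls, sum)[cls]
  dens <- if (totC == 0) rep(0, length(C)) else
    ifelse(Asum > 0, (Csum / Asum) / totC * ncell, 0)
  tab <- cbind(spec,
               data.frame(summed_count = unname(Csum),
                          summed_area_um2 = unname(Asum),
                          own_count = unname(C), own_area_um2 = unname(A),
                          density_per_um2 = unname(dens),
                          sym_class = cls))
  structure(list(table = tab, n_cells = ncell, total_counts = totC,
                 symmetrized = symmetrize, flagged = totC == 0),
            class = "densityMap")
}

#' Representative cell mask from aligned, summed masks
#'
#' Masks are aligned by centroid and long-axis orientation (nearest-pixel
#' resampling on a common canvas), summed, and thresholded at fifty
#' percent of the maximum of the summed stack.
#'
#' @param masks list of logical cell masks.
#' @return list: `mask` (logical canvas), `summed` (aligned sum).
#' @export
representativeCell <- function(masks) {
  if (length(masks) == 0) stop("need at least one mask")
  half <- ceiling(max(vapply(masks, function(m) max(dim(m)), 1)) / 2) + 2
  n <- 2 * half + 1
  canvas <- matrix(0, n, n)
  g <- coordGrid(n, n)
  dx <- g$x - half; dy <- g$y - half
  for (m in masks) {
    ax <- maskAxes(m)
    u <- ax$long; v <- c(-u[2], u[1])
    sx <- ax$center[1] + dx * u[1] + dy * v[1]
    sy <- ax$center[2] + dx * u[2] + dy * v[2]
    canvas <- canvas + matrix(maskAt(m, as.numeric(sx), as.numeric(sy)), n, n)
  }
  rep_ <- canvas >= 0.5 * max(canvas)
  ## keep the largest connected component (thresholding a unimodal sum
  ## yields one, but guard against stray pixels)
  lb <- EBImage::bwlabel(rep_)
  if (max(lb) > 1) rep_ <- lb == which.max(tabulate(lb[lb > 0]))
  list(mask = rep_, summed = canvas)
}
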