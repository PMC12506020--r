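## Synthetic microscopy scenes with ground truth.
##
## Every generator here is deterministic given its seed, and every piece of
## ground truth (positions, nucleoid pixel sets, drift, correlation) is fixed
## before noise is drawn, so downstream recovery tests compare against
## noise-free truth.

#' Camera/illumination noise model
#'
#' @param background mean offset added everywhere (a.u., >= 0).
#' @param readSigma Gaussian read-noise standard deviation (a.u., >= 0).
#' @param shotNoise logical; if TRUE the (signal + background) expectation is
#'   replaced by a Poisson draw before read noise is added.
#' @return A list with class `noiseModel`.
#' @export
noiseModel <- function(background = 100, readSigma = 5, shotNoise = FALSE) {
  stopifnot(background >= 0, readSigma >= 0, is.logical(shotNoise))
  structure(list(background = background, readSigma = readSigma,
                 shotNoise = shotNoise), class = "noiseModel")
}

## signal (no background) -> noisy image; deterministic under seed
addNoise <- function(signal, noise, seed) {
  withSeed(seed, {
    img <- signal + noise$background
    if (noise$shotNoise) img <- matrix(rpois(length(img), pmax(img, 0)),
                                       nrow(img), ncol(img))
    if (noise$readSigma > 0)
      img <- img + matrix(rnorm(length(img), 0, noise$readSigma),
                          nrow(img), ncol(img))
    pmax(img, 0)
  })
}

#' Rasterize a rod-shaped (spherocylindrical) cell mask
#'
#' The cell is a rectangle of length `lengthUm - widthUm` capped by two
#' semicircles of diameter `widthUm`: the planar cross-section of a
#' spherocylinder. A pixel belongs to the mask when its center lies within
#' `widthUm / 2` of the central axis segment.
#'
#' @param lengthUm total pole-to-pole length (um), >= widthUm.
#' @param widthUm cell width (um), > 0.
#' @param pixelSizeNm physical pixel edge (nm).
#' @param orientationDeg long-axis angle from the x axis, degrees.
#' @param marginPx border margin kept free around the rod (default 5).
#' @return Logical matrix; the rod never touches the matrix border.
#' @examples
#' m <- makeCellMask(4, 1)
#' dim(m)
#' @export
makeCellMask <- function(lengthUm, widthUm, pixelSizeNm = 60,
                         orientationDeg = 0, marginPx = 5) {
  if (!(lengthUm >= widthUm && widthUm > 0))
    stop("need lengthUm >= widthUm > 0")
  px <- pixelSizeNm / 1000                 # um per pixel
  L <- lengthUm / px; W <- widthUm / px    # in pixels
  th <- orientationDeg * pi / 180
  ext_x <- abs(cos(th)) * L + abs(sin(th)) * W
  ext_y <- abs(sin(th)) * L + abs(cos(th)) * W
  nc <- ceiling(ext_x) + 2 * marginPx
  nr <- ceiling(ext_y) + 2 * marginPx
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  h <- (L - W) / 2                         # axis segment half-length
  ax <- h * cos(th); ay <- h * sin(th)
  g <- coordGrid(nr, nc)
  ## distance from each pixel center to the segment [c - a, c + a]
  pxr <- g$x - cx; pyr <- g$y - cy
  t <- if (h > 0) pmin(pmax((pxr * ax + pyr * ay) / (h * h), -1), 1) else 0
  d2 <- (pxr - t * ax)^2 + (pyr - t * ay)^2
  mask <- d2 <= (W / 2)^2
  if (any(mask[1, ]) || any(mask[nr, ]) || any(mask[, 1]) || any(mask[, nc]))
    stop("grid too small to contain the rod with its margin")
  mask
}

#' Render diffraction-limited foci over a cell mask
#'
#' Each focus contributes an isotropic 2-D Gaussian of the given amplitude
#' and PSF sigma; the rendered image is background + sum of foci + noise,
#' clipped at zero.
#'
#' @param mask logical cell mask (defines the grid; positions must fall in it).
#' @param positions matrix/data.frame with columns x, y in pixel coordinates.
#' @param amplitudes peak amplitude per focus (recycled).
#' @param psfSigmaNm PSF standard deviation in nm (default 120, i.e. 2 px at
#'   the default 60 nm pixel size).
#' @param noise a [noiseModel()].
#' @param seed RNG seed.
#' @param pixelSizeNm physical pixel edge (nm).
#' @return Numeric intensity matrix of the same dimensions as `mask`.
#' @export
renderFoci <- function(mask, positions, amplitudes = 500, psfSigmaNm = 120,
                       noise = noiseModel(), seed = 1, pixelSizeNm = 60) {
  stopifnot(psfSigmaNm > 0)
  positions <- as.matrix(as.data.frame(positions))
  if (nrow(positions) > 0) {
    if (!all(maskAt(mask, positions[, 1], positions[, 2])))
      stop("focus positions must lie inside the mask")
    amplitudes <- rep_len(amplitudes, nrow(positions))
  }
  sig <- fociSignal(dim(mask), positions, amplitudes,
                    sigmaToPx(psfSigmaNm, pixelSizeNm))
  addNoise(sig, noise, seed)
}

fociSignal <- function(dims, positions, amplitudes, sigma_px) {
  sig <- matrix(0, dims[1], dims[2])
  if (NROW(positions) == 0) return(sig)
  g <- coordGrid(dims[1], dims[2])
  for (i in seq_len(nrow(positions))) {
    d2 <- (g$x - positions[i, 1])^2 + (g$y - positions[i, 2])^2
    sig <- sig + amplitudes[i] * exp(-d2 / (2 * sigma_px^2))
  }
  sig
}

#' Simulate a radially confined random walk
#'
#' Gaussian steps confined to the disk of radius `confinementRadiusUm` about
#' `center`: a proposed step that would leave the disk is redrawn
#' (Metropolis-style hard-wall boundary). This is the simplest confined
#' process with an exact confinement parameter, and its stationary
#' distribution is uniform over the disk at every step size, so long walks
#' have mean centroid distance 2R/3 regardless of the step/radius ratio.
#'
#' @param center numeric (x, y) in um.
#' @param confinementRadiusUm reflecting-boundary radius (um, >= 0).
#' @param stepSigmaUm per-axis step standard deviation (um).
#' @param nFrames number of positions (>= 10).
#' @param seed RNG seed.
#' @return data.frame (frame, x, y) in um; frame is 0-based.
#' @export
simulateConfinedWalk <- function(center, confinementRadiusUm, stepSigmaUm,
                                 nFrames, seed = 1) {
  stopifnot(nFrames >= 10, confinementRadiusUm >= 0, stepSigmaUm >= 0)
  R <- confinementRadiusUm
  withSeed(seed, {
    pos <- matrix(rep(as.numeric(center), each = nFrames), nFrames, 2)
    if (R > 0 && stepSigmaUm > 0) {
      p <- as.numeric(center)
      for (t in 2:nFrames) {
        repeat {
          q <- p + rnorm(2, 0, stepSigmaUm)
          if (sum((q - center)^2) <= R^2) break
        }
        p <- q
        pos[t, ] <- p
      }
    }
    data.frame(frame = 0:(nFrames - 1), x = pos[, 1], y = pos[, 2])
  })
}

#' Render a DAPI-like nucleoid channel with known true region
#'
#' The true nucleoid region is built inside a core inset from the cell
#' boundary (the nucleoid is excluded from the membrane-proximal cytoplasm,
#' up to 2 px of erosion when the target area allows it) and compressed
#' about the centroid along the chosen principal axis; the compression is
#' tuned per pixel so the region's count matches `areaFraction` of the mask
#' exactly (up to ties). The region is rendered brighter than the
#' cytoplasm, blurred with a diffraction-scale sigma (66 nm default, the
#' blue-emission diffraction limit), and noised; the returned truth is the
#' pre-blur pixel set.
#'
#' @param mask logical cell mask.
#' @param areaFraction target nucleoid area / cell area, in (0, 1].
#' @param axis `"long"` or `"short"`: the cell axis along which the region is
#'   compressed.
#' @param blurSigmaNm optical blur sigma (nm).
#' @param noise a [noiseModel()].
#' @param seed RNG seed.
#' @param pixelSizeNm physical pixel edge (nm).
#' @param cytoLevel,nucLevel cytoplasm and nucleoid signal levels above
#'   background (a.u.).
#' @return list(image, region) where region is the true logical nucleoid set.
#' @export
renderNucleoid <- function(mask, areaFraction, axis = c("long", "short"),
                           blurSigmaNm = 66, noise = noiseModel(), seed = 1,
                           pixelSizeNm = 60, cytoLevel = 50, nucLevel = 150) {
  axis <- match.arg(axis)
  if (!(areaFraction > 0 && areaFraction <= 1))
    stop("areaFraction must lie in (0, 1]")
  region <- nucleoidRegion(mask, areaFraction, axis)
  sig <- cytoLevel * mask + (nucLevel - cytoLevel) * region
  sig <- gaussBlur(sig, sigmaToPx(blurSigmaNm, pixelSizeNm))
  list(image = addNoise(sig, noise, seed), region = region)
}

## principal axes of a mask: centroid + unit long/short axis vectors
maskAxes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  cv <- cov(cbind(x - cx, y - cy))
  ev <- eigen(cv, symmetric = TRUE)
  ## canonical orientation (positive x, then positive y) so that pole
  ## selection by oscillation phase is deterministic
  canon <- function(u) if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) -u else u
  list(center = c(cx, cy), long = canon(ev$vectors[, 1]),
       short = canon(ev$vectors[, 2]), sd = sqrt(pmax(ev$values, 0)))
}

nucleoidRegion <- function(mask, areaFraction, axis) {
  if (areaFraction == 1) return(mask)
  target <- round(areaFraction * sum(mask))
  ## the nucleoid is excluded from the membrane-proximal cytoplasm: build
  ## the region inside an inset core (largest erosion, up to 2 px, that can
  ## still hold the target area)
  core <- mask
  for (e in c(2L, 1L)) {
    er <- EBImage::erode(mask * 1L, EBImage::makeBrush(2L * e + 1L, "disc")) > 0
    if (sum(er) >= target) { core <- er; break }
  }
  ax <- maskAxes(core)
  u <- if (axis == "long") ax$long else ax$short
  idx <- which(core, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  t <- (x - ax$center[1]) * u[1] + (y - ax$center[2]) * u[2]
  ## pixel p belongs to the region at compression s when the point pulled
  ## away from the centroid along u by 1/s still lands in the mask; for a
  ## spherocylinder membership is monotone in s, so each pixel has a
  ## threshold s_p found by vectorized bisection, and exact pixel-count
  ## targeting takes the `target` smallest thresholds
  member <- function(s) {
    qx <- x + t * (1 / s - 1) * u[1]
    qy <- y + t * (1 / s - 1) * u[2]
    maskAt(core, qx, qy)
  }
  lo <- rep(1e-4, length(x)); hi <- rep(1, length(x))
  for (i in 1:36) {
    mid <- (lo + hi) / 2
    m <- member(mid)
    hi[m] <- mid[m]; lo[!m] <- mid[!m]
  }
  keep <- order(hi)[seq_len(min(target, length(x)))]
  region <- mask & FALSE
  region[idx[keep, , drop = FALSE]] <- TRUE
  region
}

#' Render a ParA-like protein localization pattern
#'
#' Three pattern modes over a cell mask: `polar_gradient` (exponential
#' intensity decay from one pole, the pole selected by `phase` so a phase
#' series produces pole-to-pole oscillation), `diffuse` (uniform), and
#' `puncta` (a few bright diffraction-limited spots over a dim floor).
#'
#' @param mask logical cell mask.
#' @param mode one of `"polar_gradient"`, `"diffuse"`, `"puncta"`.
#' @param phase oscillation phase in [0, 1); the gradient emanates from one
#'   pole for phase < 0.5 and from the opposite pole otherwise.
#' @param noise a [noiseModel()].
#' @param seed RNG seed.
#' @param amplitude peak signal level above background (a.u.).
#' @param nPuncta number of spots in `puncta` mode.
#' @param decayFraction gradient decay length as a fraction of cell length.
#' @param psfSigmaPx PSF sigma (px) used for puncta rendering.
#' @return Numeric intensity matrix.
#' @export
renderMcdaPattern <- function(mask, mode, phase = 0, noise = noiseModel(),
                              seed = 1, amplitude = 300, nPuncta = 2,
                              decayFraction = 0.2, psfSigmaPx = 2) {
  if (!mode %in% c("polar_gradient", "diffuse", "puncta"))
    stop("unknown mode: ", mode)
  stopifnot(phase >= 0, phase < 1)
  sig <- mcdaSignal(mask, mode, phase, amplitude, nPuncta, decayFraction,
                    psfSigmaPx, seed)
  addNoise(sig, noise, seed)
}

mcdaSignal <- function(mask, mode, phase, amplitude, nPuncta, decayFraction,
                       psfSigmaPx, seed) {
  ax <- maskAxes(mask)
  g <- coordGrid(nrow(mask), ncol(mask))
  t <- (g$x - ax$center[1]) * ax$long[1] + (g$y - ax$center[2]) * ax$long[2]
  tin <- t[mask]
  if (mode == "diffuse") return(amplitude * mask)
  if (mode == "polar_gradient") {
    pole <- if (phase < 0.5) min(tin) else max(tin)
    lambda <- decayFraction * (max(tin) - min(tin))
    sig <- amplitude * exp(-abs(t - pole) / lambda)
    return(sig * mask)
  }
  ## puncta: spots spaced along the long axis, on the midline
  frac <- seq_len(nPuncta) / (nPuncta + 1)
  tpos <- min(tin) + frac * (max(tin) - min(tin))
  pts <- cbind(ax$center[1] + tpos * ax$long[1],
               ax$center[2] + tpos * ax$long[2])
  fociSignal(dim(mask), pts, rep(amplitude, nPuncta), psfSigmaPx) +
    0.05 * amplitude * mask
}

#' Apply a known integer stage drift to a stack
#'
#' Each frame of every channel is translated by that frame's (dy, dx);
#' pixels shifted in from outside the field are filled with a constant.
#'
#' @param stack an [ImageStack-class].
#' @param driftTruth integer matrix (nFrames x 2) of per-frame (dy, dx);
#'   the first row must be (0, 0).
#' @param fill constant used for vacated pixels (default: the noise-model
#'   default background, 100).
#' @return A drifted [ImageStack-class].
#' @export
applyDrift <- function(stack, driftTruth, fill = 100) {
  driftTruth <- as.matrix(driftTruth)
  if (any(driftTruth != round(driftTruth))) stop("drift shifts must be integer")
  if (nrow(driftTruth) != nFrames(stack))
    stop("driftTruth must have one row per frame")
  if (any(driftTruth[1, ] != 0)) stop("frame 0 drift must be (0, 0)")
  p <- stack@pixels
  for (t in seq_len(nFrames(stack))) for (ch in seq_len(nChannels(stack)))
    p[t, ch, , ] <- translateMatrix(stack@pixels[t, ch, , ],
                                    driftTruth[t, 1], driftTruth[t, 2], fill)
  initialize(stack, pixels = p)
}

#' Render a channel pair with a known pixel correlation
#'
#' In-mask pixel pairs are drawn from a bivariate normal with population
#' correlation `rho`; out-of-mask pixels carry independent background noise.
#'
#' @param mask logical mask over which the correlated pair is drawn.
#' @param rho population correlation in [-1, 1].
#' @param seed RNG seed.
#' @param meanIntensity,sdIntensity marginal mean and SD of both channels.
#' @param noise a [noiseModel()] for the out-of-mask background.
#' @return list(imageA, imageB).
#' @export
renderCorrelatedPair <- function(mask, rho, seed = 1, meanIntensity = 100,
                                 sdIntensity = 20, noise = noiseModel()) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  withSeed(seed, {
    n <- sum(mask)
    z1 <- rnorm(n); z2 <- rnorm(n)
    zb <- rho * z1 + sqrt(1 - rho^2) * z2
    mk <- function(z) {
      img <- matrix(rnorm(length(mask), noise$background, noise$readSigma),
                    nrow(mask), ncol(mask))
      img[mask] <- meanIntensity + sdIntensity * z
      pmax(img, 0)
    }
    list(imageA = mk(z1), imageB = mk(zb))
  })
}

#' Simulate a full synthetic field of view with ground truth
#'
#' Places non-overlapping rod-shaped cells on a jittered grid and renders a
#' multi-channel time lapse: `phase` (cells dark on a bright background),
#' `foci` (diffraction-limited spots on confined random walks), `mcda` (one
#' of the three protein patterns, with pole-to-pole phase alternation for
#' `polar_gradient`), and `dapi` (nucleoid of controlled area fraction).
#' All ground truth is recorded before noise is drawn.
#'
#' @param nCells number of cells.
#' @param nFrames number of time points.
#' @param fociPerCell foci per cell.
#' @param confinementRadiusUm true confinement radius of each focus walk (um).
#' @param stepSigmaUm walk step sigma (um).
#' @param areaFraction true nucleoid area fraction in (0, 1].
#' @param nucleoidAxis compression axis for the nucleoid (`"long"`/`"short"`).
#' @param mcdaMode protein pattern mode.
#' @param oscillationPeriod frames per full pole-to-pole cycle
#'   (`polar_gradient` mode).
#' @param drift `NULL` (no drift), `TRUE` (random integer drifts in
#'   \[-10, 10\]^2), or an explicit integer matrix (nFrames x 2).
#' @param cellLengthRangeUm sampled cell length range (um).
#' @param cellWidthUm cell width (um).
#' @param fociAmplitude peak focus amplitude (a.u.).
#' @param noise a [noiseModel()].
#' @param pixelSizeNm physical pixel edge (nm).
#' @param seed RNG seed.
#' @return A [SyntheticScene-class].
#' @export
simulateScene <- function(nCells = 10, nFrames = 1, fociPerCell = 3,
                          confinementRadiusUm = 0.1, stepSigmaUm = 0.05,
                          areaFraction = 0.8, nucleoidAxis = "long",
                          mcdaMode = "diffuse", oscillationPeriod = 8,
                          drift = NULL, cellLengthRangeUm = c(2.5, 4),
                          cellWidthUm = 1, fociAmplitude = 500,
                          noise = noiseModel(), pixelSizeNm = 60, seed = 1) {
  stopifnot(nCells >= 1, nFrames >= 1)
  px_um <- pixelSizeNm / 1000
  seeds <- withSeed(seed, sample.int(2^30, 6))

  ## cell geometry
  lens <- withSeed(seeds[1],
    runif(nCells, cellLengthRangeUm[1], cellLengthRangeUm[2]))
  oris <- withSeed(seeds[2], runif(nCells, -15, 15))
  cellMasks <- lapply(seq_len(nCells), function(i)
    makeCellMask(lens[i], cellWidthUm, pixelSizeNm, oris[i]))

  ## grid placement with padding; field dimensions derived from cell sizes
  perRow <- ceiling(sqrt(nCells))
  cw <- max(vapply(cellMasks, ncol, 1L)) + 14L
  chh <- max(vapply(cellMasks, nrow, 1L)) + 14L
  nr <- chh * ceiling(nCells / perRow) + 28L
  nc <- cw * perRow + 28L
  labelTruth <- matrix(0L, nr, nc)
  offsets <- matrix(0L, nCells, 2)            # (row0, col0), 0-based
  for (i in seq_len(nCells)) {
    gr <- (i - 1) %/% perRow; gc <- (i - 1) %% perRow
    r0 <- 14L + gr * chh + (chh - nrow(cellMasks[[i]])) %/% 2
    c0 <- 14L + gc * cw + (cw - ncol(cellMasks[[i]])) %/% 2
    sub <- labelTruth[r0 + seq_len(nrow(cellMasks[[i]])),
                      c0 + seq_len(ncol(cellMasks[[i]]))]
    sub[cellMasks[[i]]] <- i
    labelTruth[r0 + seq_len(nrow(cellMasks[[i]])),
               c0 + seq_len(ncol(cellMasks[[i]]))] <- sub
    offsets[i, ] <- c(r0, c0)
  }

  ## focus ground truth: confined walks around well-interior anchors
  focusTruth <- data.frame()
  confR_px <- confinementRadiusUm / px_um
  for (i in seq_len(nCells)) {
    m <- cellMasks[[i]]
    dm <- EBImage::distmap(m)
    cand <- which(dm > confR_px + 2.5, arr.ind = TRUE)
    if (nrow(cand) == 0)
      stop("confinement radius too large for the cell interior")
    pick <- withSeed(seeds[3] + i,
                     cand[sample.int(nrow(cand), fociPerCell, replace = fociPerCell > nrow(cand)), , drop = FALSE])
    for (j in seq_len(fociPerCell)) {
      cx <- (pick[j, 2] - 1 + offsets[i, 2]) * px_um
      cy <- (pick[j, 1] - 1 + offsets[i, 1]) * px_um
      w <- simulateConfinedWalk(c(cx, cy), confinementRadiusUm, stepSigmaUm,
                                max(nFrames, 10), seed = seeds[4] + 97 * i + j)
      w <- w[seq_len(nFrames), , drop = FALSE]
      focusTruth <- rbind(focusTruth, data.frame(
        cell_id = i, focus_id = (i - 1) * fociPerCell + j, frame = w$frame,
        x = w$x / px_um, y = w$y / px_um, radius_um = confinementRadiusUm))
    }
  }

  ## nucleoid truth (static across frames)
  nucMasks <- vector("list", nCells)
  nucSignalField <- matrix(0, nr, nc)
  for (i in seq_len(nCells)) {
    reg <- nucleoidRegion(cellMasks[[i]], areaFraction, nucleoidAxis)
    full <- matrix(FALSE, nr, nc)
    full[offsets[i, 1] + seq_len(nrow(reg)), offsets[i, 2] + seq_len(ncol(reg))] <- reg
    nucMasks[[i]] <- full
    sig <- 50 * cellMasks[[i]] + 100 * reg
    nucSignalField[offsets[i, 1] + seq_len(nrow(sig)),
                   offsets[i, 2] + seq_len(ncol(sig))] <-
      nucSignalField[offsets[i, 1] + seq_len(nrow(sig)),
                     offsets[i, 2] + seq_len(ncol(sig))] + sig
  }
  nucSignalField <- gaussBlur(nucSignalField, sigmaToPx(66, pixelSizeNm))

  ## phase-contrast signal: dark cells on a bright background
  phaseSignal <- gaussBlur(-80 * (labelTruth > 0), 1) + 100
  ## the noise model's background lifts this to ~200 outside cells

  phaseSeries <- if (mcdaMode == "polar_gradient")
    ((0:(nFrames - 1)) %% oscillationPeriod) / oscillationPeriod
  else rep(0, nFrames)

  ## drift truth
  driftTruth <- matrix(0L, nFrames, 2)
  if (isTRUE(drift)) {
    driftTruth <- withSeed(seeds[5], {
      d <- matrix(sample(-10:10, 2 * nFrames, replace = TRUE), nFrames, 2)
      d[1, ] <- 0L; d
    })
  } else if (is.matrix(drift)) driftTruth <- drift

  channels <- c("phase", "foci", "mcda", "dapi")
  pixels <- array(0, c(nFrames, length(channels), nr, nc))
  for (t in seq_len(nFrames)) {
    ft <- focusTruth[focusTruth$frame == t - 1, , drop = FALSE]
    fociSig <- fociSignal(c(nr, nc), cbind(ft$x, ft$y),
                          rep(fociAmplitude, nrow(ft)),
                          sigmaToPx(120, pixelSizeNm))
    mcdaSig <- matrix(0, nr, nc)
    for (i in seq_len(nCells)) {
      sig <- mcdaSignal(cellMasks[[i]], mcdaMode, phaseSeries[t],
                        amplitude = 300, nPuncta = 2, decayFraction = 0.2,
                        psfSigmaPx = 2, seed = seeds[6] + i)
      mcdaSig[offsets[i, 1] + seq_len(nrow(sig)),
              offsets[i, 2] + seq_len(ncol(sig))] <-
        mcdaSig[offsets[i, 1] + seq_len(nrow(sig)),
                offsets[i, 2] + seq_len(ncol(sig))] + sig
    }
    pixels[t, 1, , ] <- addNoise(phaseSignal, noise, seeds[1] + 1000 + t)
    pixels[t, 2, , ] <- addNoise(fociSig, noise, seeds[2] + 2000 + t)
    pixels[t, 3, , ] <- addNoise(mcdaSig, noise, seeds[3] + 3000 + t)
    pixels[t, 4, , ] <- addNoise(nucSignalField, noise, seeds[4] + 4000 + t)
  }
  stack <- ImageStack(pixels, channels, pixelSizeNm)
  if (any(driftTruth != 0))
    stack <- applyDrift(stack, driftTruth, fill = noise$background)

  new("SyntheticScene", stack = stack, labelTruth = labelTruth,
      focusTruth = focusTruth,
      nucleoidTruth = list(
        table = data.frame(cell_id = seq_len(nCells),
                           area_fraction = areaFraction,
                           axis = nucleoidAxis),
        masks = nucMasks),
      mcdaMode = mcdaMode, phaseSeries = phaseSeries,
      driftTruth = driftTruth, rhoTruth = numeric(0), seed = as.numeric(seed))
}
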