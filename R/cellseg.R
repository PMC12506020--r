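## Cell segmentation post-processing and midline-based morphology.
##
## Segmentation proper is a pluggable backend: any external model (e.g. a
## pretrained neural segmenter) can be passed as a function returning a
## label map, and a built-in inverted-threshold backend handles synthetic
## phase-contrast fields. Everything downstream depends only on the mask
## post-processing implemented here: pre-blur, hole filling, border-cell
## removal, label compaction.

#' Segment cells from a phase-contrast image
#'
#' Applies a Gaussian pre-blur (sigma 66 nm converted to pixels), runs the
#' chosen backend, fills holes inside each cell, discards cells touching
#' the image border, and compacts labels to `1..K`. An override label map
#' (e.g. a manually corrected segmentation) can be supplied in place of the
#' backend output.
#'
#' @param phaseImage numeric matrix (phase contrast; cells darker than the
#'   background for the `threshold` backend).
#' @param backend `"threshold"` (built-in invert-and-threshold via Otsu) or
#'   `"external"` (use `externalFun`).
#' @param externalFun function(image) -> integer label matrix, required for
#'   the external backend.
#' @param pixelSizeNm physical pixel edge (nm).
#' @param blurSigmaNm pre-blur sigma (nm, default 66).
#' @param override optional integer label matrix (or TIFF path readable by
#'   [tiff::readTIFF()]) that replaces the backend output before
#'   post-processing; the manual-correction hook.
#' @return A [CellLabelMap-class]; empty (all zero) with a warning when
#'   nothing is segmented.
#' @export
segmentCells <- function(phaseImage, backend = c("threshold", "external"),
                         externalFun = NULL, pixelSizeNm = 60,
                         blurSigmaNm = 66, override = NULL) {
  backend <- match.arg(backend)
  img <- gaussBlur(phaseImage, sigmaToPx(blurSigmaNm, pixelSizeNm))
  if (!is.null(override)) {
    lbl <- if (is.character(override))
      round(tiff::readTIFF(override) * 2^16) else override
  } else if (backend == "threshold") {
    rng <- range(img)
    if (diff(rng) == 0) {
      warning("flat image; empty segmentation")
      return(CellLabelMap(matrix(0L, nrow(img), ncol(img)), pixelSizeNm))
    }
    norm <- (img - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm))
    lbl <- EBImage::bwlabel(norm < th)       # cells are dark; 4-connected
  } else {
    if (!is.function(externalFun))
      stop("external backend requires externalFun")
    lbl <- externalFun(img)
  }
  lbl <- as.matrix(lbl)
  if (any(lbl < 0) || any(lbl != round(lbl)) || any(!is.finite(lbl)))
    stop("backend returned an invalid label map")
  storage.mode(lbl) <- "integer"

  ## fill holes label-wise, then drop border-touching cells
  lbl <- EBImage::fillHull(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  border <- unique(c(lbl[1, ], lbl[nr, ], lbl[, 1], lbl[, nc]))
  lbl[lbl %in% setdiff(border, 0L)] <- 0L

  ## enforce one 4-connected component per label: re-split and compact
  out <- matrix(0L, nr, nc)
  k <- 0L
  for (lab in sort(setdiff(unique(as.integer(lbl)), 0L))) {
    comp <- EBImage::bwlabel(lbl == lab)
    for (c_ in seq_len(max(comp))) {
      k <- k + 1L
      out[comp == c_] <- k
    }
  }
  if (k == 0L) warning("empty segmentation")
  CellLabelMap(out, pixelSizeNm)
}

#' Per-cell morphology from a label map
#'
#' For each cell the mask is skeletonized (Zhang-Suen thinning), spurs are
#' pruned, the longest geodesic path is kept as the midline backbone,
#' smoothed, and extended along its end tangents to the cell boundary. The
#' cell length is the arc length of this pole-to-pole midline; the width is
#' twice the mean distance-transform value along the backbone restricted to
#' the cylindrical part (points more than half a width from the poles); the
#' area comes from the pixel count.
#'
#' @param map a [CellLabelMap-class].
#' @param minAreaPx cells smaller than this many pixels are excluded with a
#'   message (skeletons are undefined at that scale; default 9).
#' @return data.frame (cell_id, length_um, width_um, area_um2) with the
#'   midlines attached as attribute `"midlines"` (a list of (x, y) polyline
#'   matrices in 0-based full-image pixel coordinates, indexed by cell id);
#'   see [getMidline()].
#' @export
cellMorphology <- function(map, minAreaPx = 9L) {
  stopifnot(is(map, "CellLabelMap"))
  px_um <- map@pixelSizeNm / 1000
  rows <- list(); mids <- list()
  for (cid in seq_len(nCells(map))) {
    m <- cellMask(map, cid)
    if (sum(m) < minAreaPx) {
      message("cell ", cid, " smaller than ", minAreaPx, " px; excluded")
      next
    }
    ## crop with padding, keep the offset to restore full-image coordinates
    idx <- which(m, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(m), max(idx[, 1]) + 2L)
    c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(m), max(idx[, 2]) + 2L)
    sub <- m[r0:r1, c0:c1]
    dm <- EBImage::distmap(sub)

    skel <- zhangSuenThin(sub)
    w0 <- 2 * mean(dm[skel])                     # first-pass width estimate
    skel <- pruneEndpoints(skel, ceiling(w0 / 2))
    backbone <- longestSkeletonPath(skel)
    if (is.null(backbone) || nrow(backbone) < 3) {
      ## near-round cell: use the long principal axis through the centroid
      ax <- maskAxes(sub)
      backbone <- rbind(ax$center - 0.5 * ax$long, ax$center,
                        ax$center + 0.5 * ax$long)
      colnames(backbone) <- c("x", "y")
    }
    mid <- smoothPolyline(backbone, 5L)
    mid <- extendToBoundary(mid, sub)

    ## width: twice the mean perpendicular distance from the midline to the
    ## subpixel mask boundary, over the cylindrical part (half a width away
    ## from each pole)
    arc <- cumArcLength(mid)
    total <- arc[length(arc)]
    samp <- resamplePolyline(mid, 1)
    sarc <- cumArcLength(samp)
    cyl <- sarc > w0 / 2 & sarc < total - w0 / 2
    ## near-round cells have no cylindrical part: measure at mid-arc only
    if (!any(cyl)) cyl <- seq_len(nrow(samp)) == which.min(abs(sarc - total / 2))
    hw <- vapply(which(cyl), function(i) {
      u <- localTangent(samp, i)
      nvec <- c(-u[2], u[1])
      (rayToBoundary(sub, samp[i, ], nvec) +
         rayToBoundary(sub, samp[i, ], -nvec)) / 2
    }, 1)
    width_px <- 2 * mean(hw)
    length_px <- max(total, width_px)            # poles cap length >= width

    mid[, 1] <- mid[, 1] + (c0 - 1); mid[, 2] <- mid[, 2] + (r0 - 1)
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = cid,
      length_um = length_px * px_um,
      width_um = width_px * px_um,
      area_um2 = sum(m) * px_um^2)
    mids[[as.character(cid)]] <- mid
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), length_um = numeric(0),
               width_um = numeric(0), area_um2 = numeric(0))
  attr(out, "midlines") <- mids
  attr(out, "pixelSizeNm") <- map@pixelSizeNm
  out
}

#' Retrieve the midline polyline of one cell
#'
#' @param morphology the result of [cellMorphology()].
#' @param cell_id cell label.
#' @return Matrix with columns x, y (0-based pixel coordinates, pole to
#'   pole).
#' @export
getMidline <- function(morphology, cell_id) {
  m <- attr(morphology, "midlines")[[as.character(cell_id)]]
  if (is.null(m)) stop("no midline for cell ", cell_id)
  m
}
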