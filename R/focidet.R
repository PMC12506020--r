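## Fluorescent focus detection: unsharp-mask sharpening, Gaussian blur,
## single-scale Laplacian-of-Gaussian filtering, local-maximum extraction,
## and raw-intensity integration over the 2r detection circle.

#' Focus-detection parameter set
#'
#' Defaults follow the tracking detector scale used for carboxysome foci:
#' blob diameter 3.0 px and quality threshold 80. Unsharp and blur settings
#' are per-channel tunables.
#'
#' @param unsharpRadius Gaussian sigma (px) of the unsharp-mask blur.
#' @param unsharpAmount unsharp gain: `img + amount * (img - blurred)`.
#' @param blurSigma post-sharpening Gaussian blur sigma (px).
#' @param blobDiameterPx LoG blob diameter (px); the filter scale is
#'   `blobDiameterPx / (2 * sqrt(2))`.
#' @param qualityThreshold minimum scale-normalized LoG response.
#' @return list of parameters for [detectFoci()].
#' @export
fociParams <- function(unsharpRadius = 2, unsharpAmount = 1, blurSigma = 1,
                       blobDiameterPx = 3, qualityThreshold = 80) {
  if (blobDiameterPx <= 0) stop("blobDiameterPx must be positive")
  list(unsharpRadius = unsharpRadius, unsharpAmount = unsharpAmount,
       blurSigma = blurSigma, blobDiameterPx = blobDiameterPx,
       qualityThreshold = qualityThreshold)
}

## scale-normalized LoG kernel (sign-flipped: bright blobs give positive
## response)
logKernel <- function(sigma) {
  r <- max(3L, ceiling(4 * sigma))
  g <- coordGrid(2 * r + 1, 2 * r + 1)
  x <- g$x - r; y <- g$y - r
  d2 <- x^2 + y^2
  k <- -(d2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-d2 / (2 * sigma^2))
  ## zero-mean so flat regions give exactly zero response
  k <- k - mean(k)
  sigma^2 * k
}

#' Detect fluorescent foci within one cell
#'
#' The in-cell image is sharpened with an unsharp mask, Gaussian-blurred,
#' and filtered with a single-scale Laplacian of Gaussian at
#' `sigma = blobDiameterPx / (2 sqrt 2)`. Local maxima of the
#' scale-normalized response above the quality threshold and inside the
#' mask are returned sorted by quality (descending, ties broken by (y, x)
#' ascending). Focus intensities are integrated from the raw image via
#' [focusIntensity()].
#'
#' @param cellImage numeric matrix (raw intensities; out-of-mask pixels are
#'   ignored by filling them with the in-mask median before filtering).
#' @param cellMask logical matrix delimiting the cell.
#' @param params a [fociParams()] list.
#' @param cell_id optional id copied into the output.
#' @param frame optional 0-based frame index copied into the output.
#' @return data.frame (cell_id, frame, x, y, r, quality, intensity); zero
#'   rows when nothing is detected or the mask is empty.
#' @export
detectFoci <- function(cellImage, cellMask, params = fociParams(),
                       cell_id = NA_integer_, frame = 0L) {
  empty <- data.frame(cell_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), r = numeric(0),
                      quality = numeric(0), intensity = numeric(0))
  if (!any(cellMask)) return(empty)
  img <- cellImage
  img[!cellMask] <- median(img[cellMask])
  ## unsharp mask, then blur
  if (params$unsharpAmount > 0 && params$unsharpRadius > 0)
    img <- img + params$unsharpAmount * (img - gaussBlur(img, params$unsharpRadius))
  img <- gaussBlur(img, params$blurSigma)
  sigma <- params$blobDiameterPx / (2 * sqrt(2))
  resp <- convolve2(img, logKernel(sigma))
  mx <- EBImage::dilate(resp, EBImage::makeBrush(3, "box"))
  cand <- which(resp >= mx & resp > params$qualityThreshold & cellMask,
                arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  det <- data.frame(cell_id = cell_id, frame = frame,
                    x = cand[, 2] - 1, y = cand[, 1] - 1,
                    r = params$blobDiameterPx / 2,
                    quality = resp[cand])
  det <- det[order(-det$quality, det$y, det$x), , drop = FALSE]
  det$intensity <- vapply(seq_len(nrow(det)), function(i)
    focusIntensity(cellImage, det$x[i], det$y[i], det$r[i]), 1)
  rownames(det) <- NULL
  det
}

#' Summed raw intensity within the 2r circle of a detection
#'
#' Sums the raw (pre-sharpening) pixel values whose centers lie within
#' Euclidean distance `2 * r` of the detection, clipped to the image.
#'
#' @param rawImage numeric matrix of raw intensities.
#' @param x,y detection coordinates (0-based pixels).
#' @param r detection scale radius (px, > 0).
#' @return Summed intensity (a.u.).
#' @export
focusIntensity <- function(rawImage, x, y, r) {
  stopifnot(r > 0)
  R <- 2 * r
  nr <- nrow(rawImage); nc <- ncol(rawImage)
  if (x + R < 0 || x - R > nc - 1 || y + R < 0 || y - R > nr - 1)
    stop("intensity circle lies entirely outside the image")
  rs <- max(1, floor(y - R) + 1):min(nr, ceiling(y + R) + 1)
  cs <- max(1, floor(x - R) + 1):min(nc, ceiling(x + R) + 1)
  sub <- rawImage[rs, cs, drop = FALSE]
  g <- coordGrid(length(rs), length(cs))
  inside <- (g$x + cs[1] - 1 - x)^2 + (g$y + rs[1] - 1 - y)^2 <= R^2
  sum(sub[inside])
}

## minimal Euclidean distance from points to a polyline (exact
## point-to-segment projection)
distToPolyline <- function(px, py, poly) {
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(poly) - 1)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1, 1]; by <- poly[i + 1, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Per-cell focus statistics
#'
#' Nearest-neighbour spacing between focus centers, perpendicular
#' (medial) distance of each focus from the cell midline, and the whole-cell
#' intensity normalized by cell length.
#'
#' @param detections data.frame from [detectFoci()] for one cell.
#' @param midline (x, y) polyline from [getMidline()].
#' @param rawImage raw intensity matrix (full frame or cell crop, matching
#'   the detection coordinates).
#' @param cellMask logical mask of the cell in the same frame.
#' @param lengthUm the cell length (um) used for intensity normalization.
#' @param pixelSizeNm physical pixel edge (nm).
#' @return list with `perFocus` data.frame (x, y, intensity,
#'   nn_spacing_um, medial_distance_um), `focus_count`, and
#'   `whole_cell_intensity_per_length` (a.u. per um).
#' @export
focusStats <- function(detections, midline, rawImage, cellMask, lengthUm,
                       pixelSizeNm = 60) {
  px_um <- pixelSizeNm / 1000
  n <- nrow(detections)
  nn <- rep(NA_real_, n)
  if (n >= 2) {
    d <- as.matrix(dist(cbind(detections$x, detections$y)))
    diag(d) <- Inf
    nn <- apply(d, 1, min) * px_um
  }
  med <- if (n > 0)
    distToPolyline(detections$x, detections$y, midline) * px_um
  else numeric(0)
  list(perFocus = data.frame(x = detections$x, y = detections$y,
                             intensity = detections$intensity,
                             nn_spacing_um = nn,
                             medial_distance_um = med),
       focus_count = n,
       whole_cell_intensity_per_length = sum(rawImage[cellMask]) / lengthUm)
}
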