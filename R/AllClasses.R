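#' ImageStack: a multi-channel fluorescence time lapse
#'
#' Pixel intensities indexed as `[time, channel, row, column]` in arbitrary
#' detector units, together with the physical pixel size and the acquisition
#' frame interval. Row/column follow the package-wide convention that user
#' coordinates are `x = column - 1`, `y = row - 1` (0-based, pixel centers at
#' integers).
#'
#' @slot pixels 4-D non-negative numeric array `[t, c, y, x]`.
#' @slot channelNames character vector, one label per channel.
#' @slot pixelSizeNm physical pixel edge in nanometers (> 0).
#' @slot frameIntervalS acquisition interval between frames in seconds.
#' @export
setClass("ImageStack",
  representation(pixels = "array", channelNames = "character",
                 pixelSizeNm = "numeric", frameIntervalS = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 4)
      return("pixels must be a 4-D array [time, channel, row, col]")
    if (dim(p)[2] != length(object@channelNames))
      return("channelNames length must equal the channel dimension")
    if (anyDuplicated(object@channelNames))
      return("channelNames must be unique")
    if (length(object@pixelSizeNm) != 1 || object@pixelSizeNm <= 0)
      return("pixelSizeNm must be a single positive number")
    if (length(object@frameIntervalS) != 1 || object@frameIntervalS <= 0)
      return("frameIntervalS must be a single positive number")
    if (any(p < 0)) return("pixel intensities must be non-negative")
    TRUE
  })

#' Construct an ImageStack
#'
#' @param pixels a 4-D array `[t, c, y, x]`, a 3-D array `[t, y, x]`
#'   (promoted to one channel), or a matrix (one frame, one channel).
#' @param channelNames channel labels; defaults to `"ch1"`, `"ch2"`, ...
#' @param pixelSizeNm physical pixel edge in nm (default 60).
#' @param frameIntervalS frame interval in seconds (default 1; the
#'   acquisition interval is experiment-specific and never assumed).
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(matrix(0, 8, 8))
#' nFrames(s)
#' @export
ImageStack <- function(pixels, channelNames = NULL, pixelSizeNm = 60,
                       frameIntervalS = 1) {
  if (is.matrix(pixels))
    pixels <- array(pixels, c(1L, 1L, nrow(pixels), ncol(pixels)))
  else if (length(dim(pixels)) == 3)
    pixels <- aperm(array(pixels, c(dim(pixels), 1L)), c(1, 4, 2, 3))
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(dim(pixels)[2]))
  new("ImageStack", pixels = pixels, channelNames = channelNames,
      pixelSizeNm = as.numeric(pixelSizeNm),
      frameIntervalS = as.numeric(frameIntervalS))
}

#' CellLabelMap: segmented cells as an integer label image
#'
#' Background is 0; cell `k` is the set of pixels labeled `k`. Labels are
#' contiguous `1..K`. Produced by [segmentCells()], whose post-processing
#' guarantees that each label is a single 4-connected component and that no
#' labeled pixel touches the image border.
#'
#' @slot labels integer matrix.
#' @slot pixelSizeNm physical pixel edge in nanometers.
#' @export
setClass("CellLabelMap",
  representation(labels = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    lb <- object@labels
    if (!is.numeric(lb) || any(lb < 0) || any(lb != round(lb)))
      return("labels must be non-negative integers")
    k <- max(lb)
    if (k > 0 && !setequal(setdiff(unique(as.integer(lb)), 0L), seq_len(k)))
      return("labels must be contiguous 1..K")
    if (length(object@pixelSizeNm) != 1 || object@pixelSizeNm <= 0)
      return("pixelSizeNm must be a single positive number")
    TRUE
  })

#' Construct a CellLabelMap
#' @param labels integer matrix (0 = background, k = cell k).
#' @param pixelSizeNm physical pixel edge in nm.
#' @return A [CellLabelMap-class] object.
#' @export
CellLabelMap <- function(labels, pixelSizeNm = 60) {
  storage.mode(labels) <- "integer"
  new("CellLabelMap", labels = labels, pixelSizeNm = as.numeric(pixelSizeNm))
}

#' SyntheticScene: a simulated field of view with full ground truth
#'
#' Bundles the rendered [ImageStack-class], the true cell label map, and the
#' per-stage ground truth used to validate every analysis module: per-focus
#' per-frame true positions and confinement radii, per-cell true nucleoid
#' pixel sets and area fractions, the protein-pattern mode and phase series,
#' the injected stage drift, and the injected channel correlation.
#'
#' @slot stack the rendered [ImageStack-class].
#' @slot labelTruth integer matrix of true cell labels.
#' @slot focusTruth data.frame (cell_id, focus_id, frame, x, y, radius_um).
#' @slot nucleoidTruth list with `table` (cell_id, area_fraction, axis) and
#'   `masks` (list of true nucleoid logical matrices, one per cell).
#' @slot mcdaMode character: polar_gradient, diffuse or puncta.
#' @slot phaseSeries numeric per-frame oscillation phase in [0, 1).
#' @slot driftTruth integer matrix (frames x 2) of (dy, dx) per frame.
#' @slot rhoTruth injected channel correlation.
#' @slot seed RNG seed the scene was built from.
#' @export
setClass("SyntheticScene",
  representation(stack = "ImageStack", labelTruth = "matrix",
                 focusTruth = "data.frame", nucleoidTruth = "list",
                 mcdaMode = "character", phaseSeries = "numeric",
                 driftTruth = "matrix", rhoTruth = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (nrow(object@driftTruth) > 0 && any(object@driftTruth[1, ] != 0))
      return("driftTruth[1, ] must be (0, 0)")
    if (length(object@rhoTruth) == 1 &&
        (object@rhoTruth < -1 || object@rhoTruth > 1))
      return("rhoTruth must lie in [-1, 1]")
    nt <- object@nucleoidTruth
    if (length(nt) && !is.null(nt$table) &&
        (any(nt$table$area_fraction < 0) || any(nt$table$area_fraction > 1)))
      return("nucleoid area fractions must lie in [0, 1]")
    TRUE
  })

## ---- generics ----

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("pixelSizeNm", function(x) standardGeneric("pixelSizeNm"))
#' @export
setGeneric("frameIntervalS", function(x) standardGeneric("frameIntervalS"))
#' @export
setGeneric("getFrame", function(x, frame, channel) standardGeneric("getFrame"))
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @export
setGeneric("cellMask", function(x, cell_id) standardGeneric("cellMask"))
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @describeIn ImageStack-class number of time points.
#' @param x object.
#' @export
setMethod("nFrames", "ImageStack", function(x) dim(x@pixels)[1])
#' @describeIn ImageStack-class number of channels.
#' @export
setMethod("nChannels", "ImageStack", function(x) dim(x@pixels)[2])
#' @describeIn ImageStack-class channel labels.
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @describeIn ImageStack-class physical pixel edge (nm).
#' @export
setMethod("pixelSizeNm", "ImageStack", function(x) x@pixelSizeNm)
#' @describeIn ImageStack-class frame interval (s).
#' @export
setMethod("frameIntervalS", "ImageStack", function(x) x@frameIntervalS)

#' @describeIn ImageStack-class extract one frame of one channel as a matrix.
#' @param frame 1-based time index.
#' @param channel 1-based channel index or channel name.
#' @export
setMethod("getFrame", "ImageStack", function(x, frame, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, x@channelNames)
    if (is.na(channel)) stop("unknown channel name")
  }
  stopifnot(frame >= 1, frame <= nFrames(x), channel >= 1, channel <= nChannels(x))
  x@pixels[frame, channel, , ]
})

#' @describeIn CellLabelMap-class number of segmented cells.
#' @export
setMethod("nCells", "CellLabelMap", function(x) max(x@labels))
#' @describeIn CellLabelMap-class physical pixel edge (nm).
#' @export
setMethod("pixelSizeNm", "CellLabelMap", function(x) x@pixelSizeNm)
#' @describeIn CellLabelMap-class the raw integer label matrix.
#' @export
setMethod("labelMatrix", "CellLabelMap", function(x) x@labels)
#' @describeIn CellLabelMap-class logical mask of one cell.
#' @param cell_id cell label.
#' @export
setMethod("cellMask", "CellLabelMap", function(x, cell_id) {
  stopifnot(cell_id >= 1, cell_id <= max(x@labels))
  x@labels == cell_id
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d frame(s) x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  channels: %s\n", paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  pixel size: %g nm, frame interval: %g s\n",
              object@pixelSizeNm, object@frameIntervalS))
})

setMethod("show", "CellLabelMap", function(object) {
  cat(sprintf("CellLabelMap: %d x %d px, %d cell(s), pixel size %g nm\n",
              nrow(object@labels), ncol(object@labels), max(object@labels),
              object@pixelSizeNm))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d cell(s), mode '%s', rho %.2f, seed %d\n",
    max(object@labelTruth), object@mcdaMode,
    if (length(object@rhoTruth)) object@rhoTruth else NA_real_,
    as.integer(object@seed)))
  show(object@stack)
})
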