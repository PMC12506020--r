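## Pearson colocalization between two fluorescence channels, per cell
## (masked pixels) or per field of view.

#' Per-cell Pearson colocalization
#'
#' Sample Pearson correlation over the in-mask pixel pairs of two
#' registered channels.
#'
#' @param channelA,channelB numeric matrices of identical dimensions.
#' @param cellMask logical matrix selecting the cell's pixels (>= 2).
#' @param cell_id optional id copied into the output.
#' @return data.frame (cell_id, pearson_r, n_pixels, flagged); `flagged`
#'   marks zero-variance input, where r is undefined (NA) and the record
#'   must be excluded from summaries.
#' @export
pearsonPerCell <- function(channelA, channelB, cellMask,
                           cell_id = NA_integer_) {
  stopifnot(all(dim(channelA) == dim(channelB)),
            all(dim(channelA) == dim(cellMask)))
  a <- channelA[cellMask]; b <- channelB[cellMask]
  if (length(a) < 2) stop("mask must contain at least 2 pixels")
  if (sd(a) == 0 || sd(b) == 0)
    return(data.frame(cell_id = cell_id, pearson_r = NA_real_,
                      n_pixels = length(a), flagged = TRUE))
  data.frame(cell_id = cell_id, pearson_r = cor(a, b),
             n_pixels = length(a), flagged = FALSE)
}

#' Whole-field Pearson colocalization
#'
#' As [pearsonPerCell()] but over every pixel of the field (no mask).
#'
#' @param channelA,channelB numeric matrices of identical dimensions.
#' @param field_id optional id copied into the output.
#' @return data.frame (cell_id, pearson_r, n_pixels, flagged).
#' @export
pearsonPerField <- function(channelA, channelB, field_id = NA_integer_) {
  pearsonPerCell(channelA, channelB,
                 matrix(TRUE, nrow(channelA), ncol(channelA)),
                 cell_id = field_id)
}

#' Pearson colocalization for every cell of a label map
#'
#' Optionally gates cells on a viability channel (e.g. chlorophyll): cells
#' whose mean gate-channel intensity is below `gateFactor` times the field
#' background (modal value outside cells) are excluded.
#'
#' @param channelA,channelB numeric matrices.
#' @param map a [CellLabelMap-class].
#' @param gateChannel optional numeric matrix used for the viability gate.
#' @param gateFactor gate threshold as a multiple of the field background
#'   (default 2).
#' @return data.frame with one row per retained cell.
#' @export
pearsonPerCellMap <- function(channelA, channelB, map, gateChannel = NULL,
                              gateFactor = 2) {
  keep <- seq_len(nCells(map))
  if (!is.null(gateChannel)) {
    bg <- modalValue(gateChannel[labelMatrix(map) == 0])
    keep <- keep[vapply(keep, function(cid)
      mean(gateChannel[cellMask(map, cid)]) > gateFactor * bg, TRUE)]
  }
  do.call(rbind, lapply(keep, function(cid)
    pearsonPerCell(channelA, channelB, cellMask(map, cid), cell_id = cid)))
}
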