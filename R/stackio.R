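## Stack I/O and drift correction.
##
## Storage layout: one multi-page 32-bit float TIFF with pages in time-major
## order (frame 1 channel 1, frame 1 channel 2, ..., frame T channel C) and a
## JSON sidecar carrying the layout and physical metadata. r-tiff stores
## samples in [0, 1] with 32-bit quantization, so pixels are divided by a
## power-of-two scale recorded in the sidecar; round trips are exact to
## 2^-32 of that scale (far below detector noise).

#' Write an ImageStack to a multi-page TIFF plus JSON sidecar
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path (`.tif`); the sidecar is written next to it
#'   with the same stem and a `.json` extension.
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  d <- dim(stack@pixels)
  mx <- max(stack@pixels)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pages[[k]] <- stack@pixels[t, ch, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(n_frames = d[1], n_channels = d[2],
               channel_names = stack@channelNames,
               pixel_size_nm = stack@pixelSizeNm,
               frame_interval_s = stack@frameIntervalS,
               intensity_scale = scale, page_order = "time_major")
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecarPath <- function(path) sub("\\.tiff?$", ".json", path)

#' Read an ImageStack written by [writeStack()]
#'
#' Fails loudly when the sidecar is missing or when the TIFF page count does
#' not match the declared time/channel layout; no silent defaults.
#'
#' @param path TIFF path.
#' @return An [ImageStack-class].
#' @export
readStack <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  need <- c("n_frames", "n_channels", "channel_names", "pixel_size_nm",
            "frame_interval_s", "intensity_scale")
  if (!all(need %in% names(meta)))
    stop("sidecar lacks required fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- meta$n_frames; nc_ <- meta$n_channels
  if (length(pages) != nt * nc_)
    stop(sprintf("page count mismatch: TIFF has %d pages, sidecar declares %d frames x %d channels = %d",
                 length(pages), nt, nc_, nt * nc_))
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent page shapes in ", path)
  px <- array(0, c(nt, nc_, dims[1, 1], dims[2, 1]))
  k <- 1L
  for (t in seq_len(nt)) for (ch in seq_len(nc_)) {
    px[t, ch, , ] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  ImageStack(px, meta$channel_names, meta$pixel_size_nm, meta$frame_interval_s)
}

## integer shift of `img` that best aligns it to `ref`, by frequency-domain
## cross-correlation of mean-subtracted, zero-padded images
crossCorrShift <- function(ref, img) {
  nr <- nrow(ref); nc <- ncol(ref)
  a <- matrix(0, 2 * nr, 2 * nc); b <- matrix(0, 2 * nr, 2 * nc)
  a[1:nr, 1:nc] <- ref - mean(ref)
  b[1:nr, 1:nc] <- img - mean(img)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) { v <- i - 1L; if (v >= n) v - 2L * n else v }
  c(dy = wrap(unname(pk[1]), nr), dx = wrap(unname(pk[2]), nc))
}

#' Register a stack to its first frame by cross-correlation
#'
#' For every frame the integer (dy, dx) shift maximizing the
#' cross-correlation of the reference channel against frame 1 is found in
#' the frequency domain (mean-subtracted, zero-padded); the same shift is
#' then applied to every channel at that time point. Vacated pixels are
#' filled with the frame's modal background value.
#'
#' @param stack an [ImageStack-class].
#' @param referenceChannel channel index or name used for shift estimation
#'   (phase contrast in typical use).
#' @param maxShiftFrac error out when a recovered shift exceeds this
#'   fraction of the frame size (default 0.25), which indicates a failed
#'   acquisition rather than stage drift.
#' @return list with `stack` (registered [ImageStack-class]) and `shifts`,
#'   a data.frame (frame, dy, dx, flat) of applied offsets; `flat` marks
#'   frames whose reference image had zero variance (shift forced to 0).
#' @export
registerStack <- function(stack, referenceChannel = 1L, maxShiftFrac = 0.25) {
  if (is.character(referenceChannel)) {
    referenceChannel <- match(referenceChannel, stack@channelNames)
    if (is.na(referenceChannel)) stop("unknown reference channel")
  }
  nt <- nFrames(stack)
  ref <- getFrame(stack, 1, referenceChannel)
  shifts <- data.frame(frame = seq_len(nt) - 1L, dy = 0L, dx = 0L,
                       flat = FALSE)
  px <- stack@pixels
  refFlat <- sd(ref) == 0
  for (t in seq_len(nt)[-1]) {
    img <- getFrame(stack, t, referenceChannel)
    if (refFlat || sd(img) == 0) {
      shifts$flat[t] <- TRUE
      next
    }
    s <- crossCorrShift(ref, img)
    if (abs(s["dy"]) > maxShiftFrac * nrow(ref) ||
        abs(s["dx"]) > maxShiftFrac * ncol(ref))
      stop(sprintf("shift (%d, %d) at frame %d exceeds %g%% of the frame size",
                   s["dy"], s["dx"], t, 100 * maxShiftFrac))
    shifts$dy[t] <- s["dy"]; shifts$dx[t] <- s["dx"]
    if (any(s != 0)) {
      for (ch in seq_len(nChannels(stack))) {
        fr <- stack@pixels[t, ch, , ]
        px[t, ch, , ] <- translateMatrix(fr, s["dy"], s["dx"], modalValue(fr))
      }
    }
  }
  if (any(shifts$flat))
    warning("flat reference frame(s) at t = ",
            paste(which(shifts$flat), collapse = ", "),
            "; shift set to (0, 0)")
  list(stack = initialize(stack, pixels = px), shifts = shifts)
}
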