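#' @import methods
#' @importFrom stats rnorm rpois runif median mad sd quantile optim dnorm pt
#'   p.adjust cor complete.cases setNames aggregate approx
#' @importFrom utils head tail write.csv read.csv
NULL

## Coordinate convention used throughout the package: x runs along matrix
## columns, y along rows, both 0-based with integer coordinates at pixel
## centers. Matrix element [r, c] therefore sits at (x, y) = (c - 1, r - 1).

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that generators are
#' bit-reproducible without disturbing the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## sigma in physical nm -> sigma in pixels
sigmaToPx <- function(sigma_nm, pixel_size_nm) sigma_nm / pixel_size_nm

## Gaussian blur that tolerates small images and sigma = 0
gaussBlur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  ## EBImage::gblur needs the kernel to fit in the image; pad reflectively
  r <- ceiling(4 * sigma_px)
  pad <- padReplicate(img, r)
  out <- EBImage::gblur(pad, sigma = sigma_px, radius = 2 * r + 1)
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE]
}

padReplicate <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  img[ri, ci, drop = FALSE]
}

## 2-D convolution with replicate padding (zero-phase), kernel odd-sized
convolve2 <- function(img, kern) {
  r <- (max(dim(kern)) - 1L) %/% 2L
  pad <- padReplicate(img, r)
  out <- EBImage::filter2(pad, kern, boundary = "replicate")
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img)), drop = FALSE]
}

## modal value of rounded intensities (used as fill after translation)
modalValue <- function(v) {
  tb <- table(round(as.numeric(v)))
  as.numeric(names(tb)[which.max(tb)])
}

## integer translation of a matrix: content moves by (dy, dx), vacated
## pixels filled with `fill`
translateMatrix <- function(m, dy, dx, fill = 0) {
  stopifnot(dy == round(dy), dx == round(dx))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

## pixel (x, y) coordinate grids for a matrix, 0-based
coordGrid <- function(nr, nc) {
  list(x = matrix(rep(0:(nc - 1), each = nr), nr, nc),
       y = matrix(rep(0:(nr - 1), nc), nr, nc))
}

## nearest-pixel membership lookup of fractional (x, y) in a logical matrix;
## half-up rounding so the lookup is consistent under integer translation
maskAt <- function(mask, x, y) {
  r <- floor(y + 0.5) + 1L; c <- floor(x + 0.5) + 1L
  ok <- r >= 1L & r <= nrow(mask) & c >= 1L & c <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  out
}

## bilinear interpolation of matrix values at fractional (x, y); points
## outside the grid are clamped to the border
bilinearAt <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(y0 + 1, x0 + 1)]
  v01 <- img[cbind(y0 + 1, x1 + 1)]
  v10 <- img[cbind(y1 + 1, x0 + 1)]
  v11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

## arc length of a polyline given as a 2-column (x, y) matrix
polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

## cumulative arc length at each vertex
cumArcLength <- function(p) {
  if (nrow(p) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}
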