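## independent brute-force LoG response + exhaustive local maxima, used as
## the oracle for the detector
bruteLoG <- function(img, sigma) {
  r <- max(3L, ceiling(4 * sigma))
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  for (i in seq_len(2 * r + 1)) for (j in seq_len(2 * r + 1)) {
    d2 <- (i - r - 1)^2 + (j - r - 1)^2
    k[i, j] <- -(d2 - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-d2 / (2 * sigma^2))
  }
  k <- sigma^2 * (k - mean(k))
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in (r + 1):(nr - r)) for (j in (r + 1):(nc - r)) {
    out[i, j] <- sum(img[(i - r):(i + r), (j - r):(j + r)] * k)
  }
  out
}

bruteMaxima <- function(resp, threshold) {
  hits <- NULL
  nr <- nrow(resp); nc <- ncol(resp)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- resp[i, j]
    if (is.na(v) || v <= threshold) next
    nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (all(v >= nb, na.rm = TRUE)) hits <- rbind(hits, c(x = j - 1, y = i - 1))
  }
  hits
}

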