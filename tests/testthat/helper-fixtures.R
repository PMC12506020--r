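## Shared test helpers; fixtures are generated in code, never stored.

## 0-based pixel-center coordinate grids (mirrors the package convention)
coordGridForTest <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  list(x = matrix(rep(0:(nc - 1), each = nr), nr, nc),
       y = matrix(rep(0:(nr - 1), nc), nr, nc))
}

## quiet noise model used by deterministic tests
quietNoise <- function(background = 0) noiseModel(background, 0, FALSE)

## a simple axis-aligned rectangle mask inside a padded grid
rectMask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

## integer translation (test-local mirror of the package helper)
translateForTest <- function(m, dy, dx, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  sr <- seq_len(nrow(m)) - dy; sc <- seq_len(ncol(m)) - dx
  okr <- sr >= 1 & sr <= nrow(m); okc <- sc >= 1 & sc <= ncol(m)
  out[okr, okc] <- m[sr[okr], sc[okc]]
  out
}

## dense polyline resampling for brute-force distance oracles
resampleForTest <- function(p, step) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  s <- seq(0, arc[length(arc)], by = step)
  cbind(approx(arc, p[, 1], s, ties = "ordered")$y,
        approx(arc, p[, 2], s, ties = "ordered")$y)
}
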