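## Morphological skeletonization (Zhang-Suen thinning) and skeleton-path
## utilities. Written here because no installed R package provides thinning;
## EBImage supplies the surrounding morphology.

## shift helpers over a logical matrix, zero-filled
shiftLog <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  sr <- seq_len(nr) - dy; sc <- seq_len(nc) - dx
  ok_r <- sr >= 1 & sr <= nr; ok_c <- sc >= 1 & sc <= nc
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c]]
  out
}

#' Zhang-Suen morphological thinning
#'
#' Reduces a binary mask to a one-pixel-wide 8-connected skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @keywords internal
zhangSuenThin <- function(mask) {
  B <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      ## neighbors clockwise from north; matrix rows grow downward so
      ## "north" is row - 1
      P2 <- shiftLog(B, -1, 0); P3 <- shiftLog(B, -1, 1)
      P4 <- shiftLog(B, 0, 1);  P5 <- shiftLog(B, 1, 1)
      P6 <- shiftLog(B, 1, 0);  P7 <- shiftLog(B, 1, -1)
      P8 <- shiftLog(B, 0, -1); P9 <- shiftLog(B, -1, -1)
      Bn <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (sub == 1)
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      else
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      del <- B & Bn >= 2 & Bn <= 6 & A == 1 & cond
      if (any(del)) { B <- B & !del; changed <- TRUE }
    }
    if (!changed) break
  }
  B
}

## count of 8-neighbors for every skeleton pixel
neighborCount8 <- function(B) {
  shiftLog(B, -1, 0) + shiftLog(B, -1, 1) + shiftLog(B, 0, 1) +
    shiftLog(B, 1, 1) + shiftLog(B, 1, 0) + shiftLog(B, 1, -1) +
    shiftLog(B, 0, -1) + shiftLog(B, -1, -1)
}

## remove endpoint pixels `iter` times (spur pruning), never emptying the
## skeleton below `minKeep` pixels
pruneEndpoints <- function(B, iter, minKeep = 3L) {
  for (i in seq_len(iter)) {
    ends <- B & neighborCount8(B) <= 1
    if (!any(ends) || sum(B) - sum(ends) < minKeep) break
    B <- B & !ends
  }
  B
}

## longest geodesic path through an 8-connected skeleton, as an ordered
## (x, y) polyline (0-based coordinates); diagonal steps weigh sqrt(2)
longestSkeletonPath <- function(B) {
  idx <- which(B, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  if (n == 1) return(cbind(x = idx[1, 2] - 1, y = idx[1, 1] - 1))
  key <- paste(idx[, 1], idx[, 2])
  id <- seq_len(n); names(id) <- key
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (d in list(c(-1, 0), c(0, -1), c(-1, -1), c(-1, 1))) {
    nb <- paste(idx[, 1] + d[1], idx[, 2] + d[2])
    hit <- nb %in% key
    from <- c(from, id[hit])
    to <- c(to, id[nb[hit]])
    w <- c(w, rep(sqrt(sum(d^2)), sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = id))
  ## double-sweep: farthest node from an arbitrary start, then farthest
  ## from that; exact on trees, which pruned skeletons effectively are
  d1 <- igraph::distances(g, v = 1)
  a <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- igraph::distances(g, v = a)
  b <- which.max(ifelse(is.finite(d2), d2, -1))
  path <- igraph::shortest_paths(g, from = a, to = b)$vpath[[1]]
  ord <- as.integer(igraph::as_ids(path))
  cbind(x = idx[ord, 2] - 1, y = idx[ord, 1] - 1)
}

## moving-average smoothing of a polyline (endpoints kept), window odd
smoothPolyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (n < 3 || window < 3) return(p)
  h <- window %/% 2
  out <- p
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    out[i, ] <- colMeans(p[j, , drop = FALSE])
  }
  out[1, ] <- p[1, ]; out[n, ] <- p[n, ]
  out
}

## unit tangent at a polyline end from its last `k` vertices;
## end = 1 (start, pointing outward) or 2 (end, pointing outward)
endTangent <- function(p, end, k = 5L) {
  n <- nrow(p)
  k <- min(k, n)
  if (end == 1) v <- p[1, ] - p[k, ] else v <- p[n, ] - p[n - k + 1, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(1, 0) else v / nv
}

## resample a polyline at (approximately) fixed arc-length steps
resamplePolyline <- function(p, step = 1) {
  arc <- cumArcLength(p)
  total <- arc[length(arc)]
  if (total == 0) return(p[1, , drop = FALSE])
  s <- seq(0, total, by = step)
  if (s[length(s)] < total) s <- c(s, total)
  cbind(x = approx(arc, p[, 1], s, ties = "ordered")$y,
        y = approx(arc, p[, 2], s, ties = "ordered")$y)
}

## unit tangent at vertex i of a polyline by central differences
localTangent <- function(p, i) {
  n <- nrow(p)
  a <- max(1, i - 2); b <- min(n, i + 2)
  v <- p[b, ] - p[a, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(1, 0) else v / nv
}

## distance from `start` along direction `u` to the subpixel mask boundary
rayToBoundary <- function(mask, start, u, step = 0.25, maxSteps = 400L) {
  d <- 0
  for (i in seq_len(maxSteps)) {
    if (!maskAt(mask, start[1] + (d + step) * u[1],
                start[2] + (d + step) * u[2]))
      return(d + step / 2)
    d <- d + step
  }
  d
}

## extend both polyline ends along their tangents to the mask boundary
## (0.25 px stepping; boundary at the midpoint of the exit step)
extendToBoundary <- function(p, mask) {
  ext <- function(end) {
    u <- endTangent(p, end)
    start <- if (end == 1) p[1, ] else p[nrow(p), ]
    q <- start; step <- 0.25
    for (i in 1:400) {
      nxt <- q + step * u
      if (!maskAt(mask, nxt[1], nxt[2])) {
        ep <- q + (step / 2) * u
        ## endpoints must stay inside the mask under rounding
        if (!maskAt(mask, ep[1], ep[2])) ep <- q
        return(ep)
      }
      q <- nxt
    }
    q
  }
  rbind(ext(1), p, ext(2))
}
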