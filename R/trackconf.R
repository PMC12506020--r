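## Particle linking (two-stage: frame-to-frame assignment, then gap
## closing between track segments) and the confinement-radius statistic.

#' Link per-frame detections into trajectories
#'
#' Stage 1 links detections of consecutive frames by solving a gated linear
#' assignment with squared-distance cost (one-to-one per frame pair;
#' detections farther apart than `linkingMaxDist` are never linked;
#' unmatched detections open new track segments). Stage 2 merges segments
#' whose end and start lie within `gapMaxDist` and at most `maxFrameGap`
#' frames apart, again by minimal total squared distance.
#'
#' @param detections data.frame with columns `frame` (integer), `x`, `y`
#'   (pixels); additional columns are carried through.
#' @param linkingMaxDist frame-to-frame gate (px; default 7.5).
#' @param gapMaxDist gap-closing gate (px; default 4.5).
#' @param maxFrameGap largest allowed frame gap when closing (default 2,
#'   i.e. one missed frame).
#' @return data.frame: `detections` plus a `track_id` column, ordered by
#'   (track_id, frame). Tracks with fewer than 2 localizations are dropped.
#' @export
linkTracks <- function(detections, linkingMaxDist = 7.5, gapMaxDist = 4.5,
                       maxFrameGap = 2) {
  if (linkingMaxDist < 0 || gapMaxDist < 0) stop("distances must be >= 0")
  det <- as.data.frame(detections)
  stopifnot(all(c("frame", "x", "y") %in% names(det)))
  det <- det[order(det$frame), , drop = FALSE]
  n <- nrow(det)
  if (n == 0) return(cbind(det, track_id = integer(0)))
  seg <- seq_len(n)                # segment id per detection (union-find)

  frames <- sort(unique(det$frame))
  byFrame <- split(seq_len(n), det$frame)
  ## stage 1: consecutive-frame assignment
  for (f in frames) {
    a_idx <- byFrame[[as.character(f)]]
    b_idx <- byFrame[[as.character(f + 1)]]
    if (is.null(a_idx) || is.null(b_idx)) next
    cost <- outer(det$x[a_idx], det$x[b_idx], "-")^2 +
            outer(det$y[a_idx], det$y[b_idx], "-")^2
    m <- gatedAssign(cost, linkingMaxDist^2)
    for (i in seq_along(a_idx)) if (!is.na(m[i]))
      seg[b_idx[m[i]]] <- seg[a_idx[i]]
  }
  ## collapse to segment tables
  segid <- match(seg, unique(seg))
  nseg <- max(segid)
  ends <- vapply(seq_len(nseg), function(s) {
    ii <- which(segid == s); ii[which.max(det$frame[ii])]
  }, 1L)
  starts <- vapply(seq_len(nseg), function(s) {
    ii <- which(segid == s); ii[which.min(det$frame[ii])]
  }, 1L)

  ## stage 2: gap closing between segment ends and starts
  ef <- det$frame[ends]; sf <- det$frame[starts]
  gap <- outer(ef, sf, function(e, s) s - e)
  d2 <- outer(det$x[ends], det$x[starts], "-")^2 +
        outer(det$y[ends], det$y[starts], "-")^2
  feas <- gap >= 2 & gap <= maxFrameGap & d2 <= gapMaxDist^2
  if (any(feas)) {
    cost <- d2
    cost[!feas] <- gapMaxDist^2 * 1e6 + 1    # beyond the gate
    m <- gatedAssign(cost, gapMaxDist^2)
    nxt <- rep(NA_integer_, nseg)
    for (i in seq_len(nseg)) {
      if (!is.na(m[i]) && feas[i, m[i]] && m[i] != i) nxt[i] <- m[i]
    }
    ## merge chains end -> start
    hasPrev <- rep(FALSE, nseg); hasPrev[nxt[!is.na(nxt)]] <- TRUE
    for (s in which(!hasPrev)) {
      cur <- s
      while (!is.na(nxt[cur])) {
        segid[segid == nxt[cur]] <- s
        cur2 <- nxt[cur]; nxt[cur] <- NA_integer_; cur <- cur2
      }
    }
  }
  segid <- match(segid, unique(segid))
  det$track_id <- segid
  ## drop single-localization tracks, renumber, order
  keep <- det$track_id %in% which(tabulate(det$track_id) >= 2)
  det <- det[keep, , drop = FALSE]
  det$track_id <- match(det$track_id, unique(det$track_id))
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Confinement radius of a trajectory
#'
#' The trajectory is cropped to its first ten localizations; the radius is
#' the mean Euclidean distance of the cropped coordinates from their
#' centroid (the average xy position of the cropped track).
#'
#' @param track data.frame with columns `frame`, `x`, `y` (pixels) for one
#'   trajectory; >= 2 localizations.
#' @param pixelSizeNm physical pixel edge (nm) used for the um conversion.
#' @return list: `radius_px`, `radius_um`, `n_used` (<= 10).
#' @export
confinementRadius <- function(track, pixelSizeNm = 60) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2)
    stop("confinement radius undefined for single-localization tracks")
  use <- head(track, 10)
  cx <- mean(use$x); cy <- mean(use$y)
  r_px <- mean(sqrt((use$x - cx)^2 + (use$y - cy)^2))
  list(radius_px = r_px, radius_um = r_px * pixelSizeNm / 1000,
       n_used = nrow(use))
}

#' Confinement radii for all tracks in a linked table
#'
#' @param tracks output of [linkTracks()].
#' @param pixelSizeNm physical pixel edge (nm).
#' @return data.frame (track_id, radius_px, radius_um, n_used).
#' @export
confinementRadii <- function(tracks, pixelSizeNm = 60) {
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(id) {
    cr <- confinementRadius(tracks[tracks$track_id == id, ], pixelSizeNm)
    data.frame(track_id = id, radius_px = cr$radius_px,
               radius_um = cr$radius_um, n_used = cr$n_used)
  }))
}
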