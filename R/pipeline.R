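## Experiment orchestration: run every analysis stage over a synthetic
## scene (or user-supplied stack + labels), collect per-cell metrics,
## remove outliers by ROUT, and summarize replicates.

#' Robust outlier detection (ROUT) for a vector of values
#'
#' ROUT applied to the constant model: the robust center is the median;
#' the robust scale is the 68.27th percentile of the absolute residuals
#' inflated by `n / (n - K)` (K = 1 parameter), the robust standard
#' deviation of the residuals. Each point gets a two-sided t-tail
#' P-value at `n - K` degrees of freedom, and points are flagged by a
#' Benjamini-Hochberg false-discovery step at rate `Q` applied from the
#' most extreme residual inward.
#'
#' @param values numeric vector.
#' @param Q FDR rate (default 0.01, the method's conventional 1%).
#' @return list: `retained`, `outliers`, `is_outlier` (logical per input
#'   value), `flagged` (TRUE when n < 5, where no removal is attempted).
#' @export
removeOutliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 5)
    return(list(retained = values, outliers = values[0],
                is_outlier = rep(FALSE, n), flagged = TRUE))
  center <- median(values)
  res <- values - center
  rsdr <- unname(quantile(abs(res), 0.6827)) * n / (n - 1)
  is_out <- rep(FALSE, n)
  if (rsdr == 0) {
    ## degenerate scale: any nonzero residual is infinitely many SDs out
    is_out <- res != 0
  } else {
    p <- 2 * pt(abs(res) / rsdr, df = n - 1, lower.tail = FALSE)
    ord <- order(p)                     # most extreme first
    thr <- Q * seq_len(n) / n
    pass <- p[ord] < thr
    k <- if (any(pass)) max(which(pass)) else 0L
    if (k > 0) is_out[ord[seq_len(k)]] <- TRUE
  }
  list(retained = values[!is_out], outliers = values[is_out],
       is_outlier = is_out, flagged = FALSE)
}

#' Summarize pooled replicates per condition
#'
#' Technical replicates are pooled; per condition and biological
#' replicate, each metric is summarized by median and interquartile range
#' plus mean and SD (linear-interpolation quantiles) after ROUT outlier
#' removal.
#'
#' @param records data.frame with `condition`, `replicate` and metric
#'   columns.
#' @param metrics character vector of metric column names.
#' @param Q ROUT FDR rate.
#' @return data.frame (condition, replicate, metric, n, n_removed,
#'   median, q25, q75, mean, sd).
#' @export
summarizeReplicates <- function(records,
                                metrics = setdiff(names(records),
                                                  c("condition", "replicate",
                                                    "cell_id")),
                                Q = 0.01) {
  if (!all(c("condition", "replicate") %in% names(records)))
    stop("records must carry condition and replicate labels")
  out <- list()
  for (cond in unique(records$condition)) {
    for (rep_ in unique(records$replicate[records$condition == cond])) {
      sub <- records[records$condition == cond & records$replicate == rep_, ]
      for (mt in metrics) {
        v <- sub[[mt]]
        v <- v[is.finite(v)]
        ro <- removeOutliers(v, Q)
        r <- ro$retained
        out[[length(out) + 1]] <- data.frame(
          condition = cond, replicate = rep_, metric = mt,
          n = length(r), n_removed = length(v) - length(r),
          median = median(r), q25 = unname(quantile(r, 0.25)),
          q75 = unname(quantile(r, 0.75)), mean = mean(r), sd = sd(r))
      }
    }
  }
  do.call(rbind, out)
}

## run one stage with an informative abort message
runStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline over one scene
#'
#' Executes register, segment, morphology, focus detection, tracking and
#' confinement, nucleoid scoring, oscillation scoring, colocalization, and
#' the cell-frame density map over a [SyntheticScene-class] (generated
#' from `sceneArgs` when not supplied), and returns every intermediate
#' table plus a per-cell metrics record and a run manifest.
#'
#' @param sceneArgs list of arguments for [simulateScene()].
#' @param scene optionally a ready [SyntheticScene-class]; overrides
#'   `sceneArgs`.
#' @param condition,replicate labels copied into the metrics records.
#' @param fociParamsList a [fociParams()] list for the focus channel.
#' @param outDir optional directory; when set, all tables are written as
#'   CSV and the manifest as JSON.
#' @return list: `labelMap`, `morphology`, `detections`, `tracks`,
#'   `confinement`, `nucleoid`, `oscillation`, `coloc`, `density`,
#'   `cellMetrics`, `shifts`, `manifest`, `scene`.
#' @export
runExperiment <- function(sceneArgs = list(), scene = NULL,
                          condition = "cond", replicate = 1L,
                          fociParamsList = fociParams(), outDir = NULL) {
  if (is.null(scene))
    scene <- runStage("simulate", do.call(simulateScene, sceneArgs))
  st <- scene@stack

  reg <- runStage("register", registerStack(st, "phase"))
  st <- reg$stack

  seg <- runStage("segment", segmentCells(getFrame(st, 1, "phase"),
                                          pixelSizeNm = pixelSizeNm(st)))
  if (nCells(seg) == 0) stop("stage 'segment' failed: no cells found")
  morph <- runStage("morphology", cellMorphology(seg))

  ## focus detection on every frame of the focus channel, per cell
  det <- runStage("detect", {
    out <- list()
    for (t in seq_len(nFrames(st))) {
      img <- getFrame(st, t, "foci")
      for (cid in morph$cell_id)
        out[[length(out) + 1]] <-
          detectFoci(img, cellMask(seg, cid), fociParamsList,
                     cell_id = cid, frame = t - 1L)
    }
    do.call(rbind, out)
  })

  tracks <- runStage("track", {
    if (nFrames(st) >= 2 && nrow(det) > 0) {
      tl <- lapply(split(det, det$cell_id), linkTracks)
      off <- 0L
      tl <- lapply(tl, function(d) {
        if (nrow(d)) { d$track_id <- d$track_id + off; off <<- max(d$track_id) }
        d
      })
      do.call(rbind, tl)
    } else det[0, ]
  })
  conf <- runStage("confinement", {
    if (nrow(tracks)) {
      cr <- confinementRadii(tracks, pixelSizeNm(st))
      cr$cell_id <- vapply(cr$track_id, function(id)
        tracks$cell_id[match(id, tracks$track_id)], 1)
      cr
    } else data.frame(track_id = integer(0), radius_px = numeric(0),
                      radius_um = numeric(0), n_used = integer(0),
                      cell_id = integer(0))
  })

  nuc <- runStage("nucleoid",
                  nucleoidMorphology(getFrame(st, 1, "dapi"), seg))
  osc <- runStage("oscillation",
                  oscillationScores(getFrame(st, 1, "mcda"), seg))
  col <- runStage("coloc",
                  pearsonPerCellMap(getFrame(st, 1, "foci"),
                                    getFrame(st, 1, "mcda"), seg))
  dens <- runStage("map", {
    d1 <- det[det$frame == 0, , drop = FALSE]
    densityMap(binLocalizations(d1, seg, morph))
  })

  ## per-cell metrics record
  cm <- runStage("metrics", {
    do.call(rbind, lapply(morph$cell_id, function(cid) {
      m <- cellMask(seg, cid)
      d1 <- det[det$cell_id == cid & det$frame == 0, , drop = FALSE]
      fs <- focusStats(d1, getMidline(morph, cid), getFrame(st, 1, "foci"),
                       m, morph$length_um[morph$cell_id == cid],
                       pixelSizeNm(st))
      data.frame(
        condition = condition, replicate = replicate, cell_id = cid,
        focus_count = fs$focus_count,
        focus_intensity = if (fs$focus_count) median(d1$intensity) else NA,
        nn_spacing_um = median(fs$perFocus$nn_spacing_um),
        medial_distance_um = if (fs$focus_count)
          median(fs$perFocus$medial_distance_um) else NA,
        intensity_per_length = fs$whole_cell_intensity_per_length,
        s_comp = nuc$table$s_comp[nuc$table$cell_id == cid],
        oscillation_score =
          osc$oscillation_score[osc$cell_id == cid],
        pearson_r = if (cid %in% col$cell_id)
          col$pearson_r[col$cell_id == cid] else NA,
        confinement_um = if (any(conf$cell_id == cid))
          median(conf$radius_um[conf$cell_id == cid]) else NA)
    }))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rodmap")),
    seed = scene@seed,
    condition = condition, replicate = replicate,
    n_cells_segmented = nCells(seg),
    n_cells_measured = nrow(morph),
    n_detections = nrow(det), n_tracks = length(unique(tracks$track_id)),
    config_hash = configHash(list(sceneArgs = sceneArgs,
                                  fociParams = fociParamsList)))

  res <- list(labelMap = seg, morphology = morph, detections = det,
              tracks = tracks, confinement = conf, nucleoid = nuc,
              oscillation = osc, coloc = col, density = dens,
              cellMetrics = cm, shifts = reg$shifts, manifest = manifest,
              scene = scene)
  if (!is.null(outDir)) writeExperiment(res, outDir)
  res
}

configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Write all experiment tables to a directory
#'
#' @param result list from [runExperiment()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, nm)
    write.csv(df, file.path(outDir, nm), row.names = FALSE)
  wr(result$morphology, "morphology.csv")
  wr(result$detections, "detections.csv")
  wr(result$tracks, "tracks.csv")
  wr(result$confinement, "confinement.csv")
  wr(result$nucleoid$table, "nucleoid.csv")
  wr(result$oscillation, "oscillation.csv")
  wr(result$coloc, "coloc.csv")
  wr(result$density$table, "density_map.csv")
  wr(result$cellMetrics, "cell_metrics.csv")
  wr(result$shifts, "shifts.csv")
  jsonlite::write_json(result$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
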