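#' Read a run configuration file
#'
#' Run configurations are flat key/value YAML files; unknown keys raise a
#' validation error naming them. Recognized keys are the arguments of
#' [timelapseConfig()] (scalars and per-channel maps), plus \code{outDir},
#' \code{minPeakSnr} and \code{radiusNm}.
#'
#' @param path YAML file.
#' @return named list of validated configuration values.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(names(formals(timelapseConfig)), "outDir", "minPeakSnr",
             "radiusNm")
  unknown <- setdiff(names(cfg), known)
  stopIfNot(length(unknown) == 0,
            paste("unknown configuration keys:",
                  paste(unknown, collapse = ", ")))
  cfg
}

#' Run the simulate-detect-quantify-summarize pipeline
#'
#' End-to-end driver over the package's stages: generate a synthetic
#' two-channel time lapse, detect foci at every time point, compute
#' per-cell statistics, run the colocalization time course with chance
#' baselines, and export width profiles. All outputs (CSV tables plus a
#' JSON run manifest capturing the configuration, seed and package
#' version) go under \code{outDir}; inputs are never mutated and identical
#' configurations reproduce byte-identical tables.
#'
#' @param config list from [readRunConfig()] or arguments for
#'   [timelapseConfig()]; may contain \code{outDir}, \code{minPeakSnr},
#'   \code{radiusNm}.
#' @param outDir output directory (created); overrides \code{config$outDir}.
#' @return invisibly, a list with the main result tables.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  outDir <- outDir %||% config$outDir %||% stop("outDir required")
  config$outDir <- NULL
  minPeakSnr <- config$minPeakSnr %||% 3
  radiusNm <- config$radiusNm %||% 218
  config$minPeakSnr <- NULL; config$radiusNm <- NULL
  if (!is.null(config$focusDensity))
    config$focusDensity <- unlist(config$focusDensity)
  tlConfig <- do.call(timelapseConfig, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  tl <- generateTimelapse(tlConfig)
  tps <- seq(0, tlConfig@duration, by = tlConfig@interval)

  detected <- list()
  statsRows <- list()
  for (ti in seq_along(tps)) {
    for (fd in seq_along(tl@frames)) {
      inField <- unique(tl@cellTable$cell_id[tl@cellTable$field == fd])
      cset <- methods::new("CellSet",
        cells = Filter(function(x) x@cellId %in% inField,
                       tl@cells[[ti]]@cells))
      for (ch in tlConfig@channels) {
        fs <- detectFoci(tl@frames[[fd]][[ti]][[ch]], cset,
                         minPeakSnr = minPeakSnr,
                         psfSigmaPx = tlConfig@psfSigmaPx,
                         pixelSize = tlConfig@pixelSize, channel = ch,
                         timePoint = tps[ti])
        detected[[length(detected) + 1L]] <- foci(fs)
        if (ch == tlConfig@channels[1]) {
          st <- perCellStats(fs, cset, image = tl@frames[[fd]][[ti]][[ch]],
                             pixelSize = tlConfig@pixelSize)
          statsRows[[length(statsRows) + 1L]] <- st$perCell
        }
      }
    }
  }
  detTab <- do.call(rbind, detected)
  statTab <- do.call(rbind, statsRows)

  detSet <- methods::new("FocusSet", records = detTab,
                         pixelSize = tlConfig@pixelSize)
  utils::write.csv(detTab, file.path(outDir, "foci_detected.csv"),
                   row.names = FALSE)
  writeFociCsv(tl@foci, file.path(outDir, "foci_ground_truth.csv"))
  utils::write.csv(statTab, file.path(outDir, "per_cell_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(tl@cellTable, file.path(outDir, "cells.csv"),
                   row.names = FALSE)

  chans <- tlConfig@channels
  coloc <- NULL
  if (length(chans) >= 2 &&
      all(vapply(chans[1:2], function(ch)
        any(detTab$channel == ch), logical(1)))) {
    coloc <- tryCatch(colocalizationTimecourse(
      detTab[detTab$channel == chans[1], ],
      detTab[detTab$channel == chans[2], ],
      cellsByTime = tl@cells, radiusNm = radiusNm),
      warning = function(w) suppressWarnings(colocalizationTimecourse(
        detTab[detTab$channel == chans[1], ],
        detTab[detTab$channel == chans[2], ],
        cellsByTime = tl@cells, radiusNm = radiusNm)),
      error = function(e) NULL)
    if (!is.null(coloc))
      utils::write.csv(coloc, file.path(outDir, "colocalization.csv"),
                       row.names = FALSE)
  }

  # width profile of the first channel, pooled over time
  wcs <- unlist(lapply(seq_along(tps), function(ti) {
    ft <- detTab[detTab$channel == chans[1] &
                   detTab$time_point == tps[ti], , drop = FALSE]
    cs <- tl@cells[[ti]]
    ids <- vapply(cs@cells, cellId, character(1))
    unlist(lapply(seq_len(nrow(ft)), function(r) {
      cell <- cs[[match(ft$cell_id[r], ids)]]
      tryCatch(widthCoordinate(ft$x_um[r], ft$y_um[r], cell),
               error = function(e) NA_real_)
    }))
  }))
  wp <- widthHistogram(wcs[is.finite(wcs)])
  utils::write.csv(data.frame(width_um = wp@mids, count = wp@counts),
                   file.path(outDir, "width_profile.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "FociTrace",
    version = as.character(utils::packageVersion("FociTrace")),
    seed = tlConfig@seed,
    minPeakSnr = minPeakSnr, radiusNm = radiusNm,
    config = config)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(timelapse = tl, detected = detSet, perCell = statTab,
                 colocalization = coloc, widthProfile = wp))
}
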