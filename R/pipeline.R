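.asManifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest))
      stop("configuration error: manifest not found: ", manifest,
           call. = FALSE)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("configuration error: manifest must be a non-empty data.frame ",
         "or CSV path", call. = FALSE)
  req <- c("path", "group")
  if (!all(req %in% names(manifest)))
    stop("configuration error: manifest needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (is.null(manifest$channel_a)) manifest$channel_a <- "mito"
  if (is.null(manifest$channel_b)) manifest$channel_b <- "protein"
  if (is.null(manifest$roi)) manifest$roi <- NA_character_
  if (is.null(manifest$image)) manifest$image <- basename(manifest$path)
  manifest
}

#' Per-group mean and SEM summaries
#'
#' @param results per-image results table from [runBatch()].
#' @return data.frame with one row per group: n, mean and standard error
#'   of the mean (sample SD / sqrt(n)) for the proximity index and the
#'   percent overlap.
#' @export
groupSummaries <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(results, results$group), function(d) {
    data.frame(group = d$group[1L], n = nrow(d),
               mean_proximity = mean(d$proximity_index),
               sem_proximity = sem(d$proximity_index),
               mean_overlap_percent = mean(d$overlap_percent),
               sem_overlap_percent = sem(d$overlap_percent))
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

.logLine <- function(con, event, payload = list()) {
  if (is.null(con)) return(invisible())
  rec <- c(list(event = event), payload)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
             con)
}

#' Run the full pipeline over a manifest of images
#'
#' For every manifest row the image is read, the two channels are
#' preprocessed and thresholded into binary masks (optionally restricted to
#' an ROI), and both statistics — percent overlap and the sliding-window
#' proximity index — are computed, yielding one row of the results table.
#' Group means with SEM are attached. A failing image is logged and
#' skipped; the run continues.
#'
#' @param manifest data.frame or CSV path with columns \code{path},
#'   \code{group} and optionally \code{image} (identifier),
#'   \code{channel_a}, \code{channel_b} (labels, default
#'   \code{"mito"}/\code{"protein"}) and \code{roi} (mask path).
#' @param channelNames optional labels assigned to the planes of every
#'   image on read (needed when the TIFFs carry no usable channel order
#'   beyond plane order).
#' @param preprocess a [PreprocessParams-class].
#' @param specA,specB per-channel [ThresholdSpec-class]s.
#' @param config a [ProximityConfig-class].
#' @param outDir optional output directory; when given,
#'   \code{results.csv}, \code{summaries.csv} and \code{run.log.jsonl}
#'   are written there.
#' @param keepMasks also return the per-image mask pairs (for e.g.
#'   [windowSizeSweep()]).
#' @return A list with \code{results} (per-image data.frame),
#'   \code{summaries} (per-group data.frame), \code{nFailed}, and — when
#'   \code{keepMasks} — \code{masks}, a per-image list of mask pairs with
#'   a \code{group} attribute each.
#' @export
runBatch <- function(manifest, channelNames = NULL,
                     preprocess = PreprocessParams(),
                     specA = ThresholdSpec(), specB = specA,
                     config = ProximityConfig(),
                     outDir = NULL, keepMasks = FALSE) {
  manifest <- .asManifest(manifest)
  logCon <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logCon <- file(file.path(outDir, "run.log.jsonl"), open = "wt")
    on.exit(close(logCon))
  }
  .logLine(logCon, "run_start", list(
    package_version = as.character(utils::packageVersion("ColocProx")),
    n_images = nrow(manifest), k = config@k, stride = config@stride,
    edge_policy = config@edgePolicy,
    median_radius = preprocess@medianRadius,
    tophat_radius = preprocess@tophatRadius,
    threshold_method_a = specA@method, threshold_method_b = specB@method))

  rows <- list()
  masks <- list()
  nFailed <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- readMultiChannelImage(row$path, channelNames = channelNames)
      roi <- if (!is.na(row$roi) && nzchar(row$roi)) readRoiMask(row$roi)
      warns <- character()
      pair <- withCallingHandlers(
        segmentPair(img, row$channel_a, row$channel_b,
                    params = preprocess, specA = specA, specB = specB,
                    roi = roi),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      ov <- withCallingHandlers(
        percentOverlap(pair[[1L]], pair[[2L]]),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      px <- proximityIndex(pair[[1L]], pair[[2L]], config)
      rec <- data.frame(
        image = row$image, group = row$group,
        k = config@k, window_size = windowSize(config),
        common = commonCount(ov), union = unionCount(ov),
        overlap = overlapFraction(ov), overlap_percent = overlapPercent(ov),
        n_nonzero_windows = nNonzeroWindows(px),
        proximity_index = overallIndex(px),
        threshold_a = realizedThreshold(pair[[1L]]),
        threshold_b = realizedThreshold(pair[[2L]]))
      .logLine(logCon, "image", c(as.list(rec),
                                  list(warnings = warns)))
      list(rec = rec, pair = pair, group = row$group)
    }, error = function(e) {
      .logLine(logCon, "image_error",
               list(image = row$image, message = conditionMessage(e)))
      warning("image '", row$image, "' failed and was skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      nFailed <- nFailed + 1L
    } else {
      rows[[length(rows) + 1L]] <- res$rec
      if (keepMasks) {
        mp <- res$pair
        attr(mp, "group") <- res$group
        masks[[res$rec$image]] <- mp
      }
    }
  }
  if (length(rows) == 0L)
    stop("every image in the manifest failed", call. = FALSE)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summaries <- groupSummaries(results)
  .logLine(logCon, "run_end", list(n_ok = nrow(results), n_failed = nFailed))

  if (!is.null(outDir)) {
    utils::write.csv(results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(outDir, "summaries.csv"),
                     row.names = FALSE)
  }
  out <- list(results = results, summaries = summaries, nFailed = nFailed)
  if (keepMasks) out$masks <- masks
  out
}

#' Synthetic two-group benchmark
#'
#' Generates a matched pair of treatment-like groups — "colocalized"
#' (protein fully recruited onto the mitochondrial network) and "control"
#' (membrane-associated protein) — writes the scenes as TIFFs, runs the
#' full pipeline (preprocess, Otsu segmentation, both statistics) and a
#' window-size sweep over the segmented masks, and returns all tables.
#'
#' @param baseSeed integer seed driving every scene.
#' @param nPerGroup scenes per group (>= 2).
#' @param imageSize side of the square scenes in pixels.
#' @param kRange window exponents for the sweep; capped so the largest
#'   window fits the scenes.
#' @param outDir optional output directory for scenes, tables
#'   (\code{results.csv}, \code{summaries.csv}, \code{sweep.csv}) and the
#'   run log; defaults to a temporary directory.
#' @param noiseScale noise gain forwarded to the scene generator.
#' @return A list with \code{results}, \code{summaries}, \code{sweep}
#'   (a [SweepResult-class]) and \code{outDir}.
#' @export
runSyntheticBenchmark <- function(baseSeed = 1L, nPerGroup = 10L,
                                  imageSize = 256L, kRange = 2:8,
                                  outDir = NULL, noiseScale = 5) {
  if (nPerGroup < 2L)
    stop("configuration error: nPerGroup must be >= 2", call. = FALSE)
  if (is.null(outDir)) outDir <- tempfile("benchmark")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  kRange <- kRange[2L^kRange <= imageSize]

  mk <- function(mode) SceneConfig(height = imageSize, width = imageSize,
                                   proteinMode = mode, colocFraction = 1,
                                   displacement = 0, noiseScale = noiseScale)
  configs <- c(replicate(nPerGroup, mk("mito_colocalized"), simplify = FALSE),
               replicate(nPerGroup, mk("membrane"), simplify = FALSE))
  labels <- rep(c("colocalized", "control"), each = nPerGroup)
  scenes <- sceneBatch(configs, labels, baseSeed = baseSeed)

  sceneDir <- file.path(outDir, "scenes")
  dir.create(sceneDir, showWarnings = FALSE)
  paths <- vapply(names(scenes), function(id) {
    writeScene(scenes[[id]], file.path(sceneDir, id))
  }, character(1))
  manifest <- data.frame(image = names(scenes), path = unname(paths),
                         group = labels)

  run <- runBatch(manifest, channelNames = c("mito", "protein"),
                  outDir = outDir, keepMasks = TRUE)

  grouped <- split(run$masks,
                   vapply(run$masks, attr, character(1), "group"))
  sweep <- windowSizeSweep(grouped, kRange = kRange)
  sweepTab <- perKGroupMeans(sweep)
  sweepTab$separation <- separation(sweep)[as.character(sweepTab$k)]
  sweepTab$selected_k <- selectedK(sweep)
  utils::write.csv(sweepTab, file.path(outDir, "sweep.csv"),
                   row.names = FALSE)

  list(results = run$results, summaries = run$summaries, sweep = sweep,
       outDir = outDir)
}
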