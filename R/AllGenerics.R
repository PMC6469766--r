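#' Channel labels of an image
#' @param x a [MultiChannelImage-class].
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @aliases channelNames,MultiChannelImage-method
setMethod("channelNames", "MultiChannelImage", function(x) names(x@pixels))

#' Extract one channel as a matrix
#' @param x a [MultiChannelImage-class].
#' @param channel channel label.
#' @return numeric matrix of intensities.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname getChannel
#' @aliases getChannel,MultiChannelImage-method
setMethod("getChannel", "MultiChannelImage", function(x, channel) {
  if (!channel %in% names(x@pixels))
    stop("configuration error: unknown channel '", channel,
         "'; available: ", paste(names(x@pixels), collapse = ", "),
         call. = FALSE)
  x@pixels[[channel]]
})

#' @describeIn MultiChannelImage height and width in pixels.
#' @param x a MultiChannelImage.
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@pixels[[1L]]))

#' Pixel grid of a mask
#' @param x a [BinaryMask-class] or [RoiMask-class].
#' @return the underlying matrix (numeric 0/1 or logical).
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname maskPixels
#' @aliases maskPixels,BinaryMask-method
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)

#' @rdname maskPixels
#' @aliases maskPixels,RoiMask-method
setMethod("maskPixels", "RoiMask", function(x) x@pixels)

#' @describeIn BinaryMask mask height and width.
#' @param x a BinaryMask.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@pixels))

#' Realized segmentation threshold
#' @param x a [BinaryMask-class].
#' @return the intensity threshold applied (NA if not applicable).
#' @export
setGeneric("realizedThreshold", function(x) standardGeneric("realizedThreshold"))

#' @rdname realizedThreshold
#' @aliases realizedThreshold,BinaryMask-method
setMethod("realizedThreshold", "BinaryMask", function(x) x@threshold)

#' Overlap fraction (common / union)
#' @param x an [OverlapResult-class].
#' @return fraction in [0, 1].
#' @export
setGeneric("overlapFraction", function(x) standardGeneric("overlapFraction"))

#' @rdname overlapFraction
#' @aliases overlapFraction,OverlapResult-method
setMethod("overlapFraction", "OverlapResult", function(x) x@overlap)

#' Overlap percentage (100 * common / union)
#' @param x an [OverlapResult-class].
#' @return percentage in [0, 100].
#' @export
setGeneric("overlapPercent", function(x) standardGeneric("overlapPercent"))

#' @rdname overlapPercent
#' @aliases overlapPercent,OverlapResult-method
setMethod("overlapPercent", "OverlapResult", function(x) x@overlapPercent)

#' AND / OR pixel counts of an overlap result
#' @param x an [OverlapResult-class].
#' @return pixel count.
#' @export
setGeneric("commonCount", function(x) standardGeneric("commonCount"))

#' @rdname commonCount
#' @aliases commonCount,OverlapResult-method
setMethod("commonCount", "OverlapResult", function(x) x@common)

#' @rdname commonCount
#' @export
setGeneric("unionCount", function(x) standardGeneric("unionCount"))

#' @rdname commonCount
#' @aliases unionCount,OverlapResult-method
setMethod("unionCount", "OverlapResult", function(x) x@union)

#' Window side length in pixels (2^k)
#' @param x a [ProximityConfig-class] or [ProximityResult-class].
#' @return window side in pixels.
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))

#' @rdname windowSize
#' @aliases windowSize,ProximityConfig-method
setMethod("windowSize", "ProximityConfig", function(x) 2L^x@k)

#' @rdname windowSize
#' @aliases windowSize,ProximityResult-method
setMethod("windowSize", "ProximityResult", function(x) 2L^x@config@k)

#' Overall proximity index of a result
#' @param x a [ProximityResult-class].
#' @return index in [0, 1].
#' @export
setGeneric("overallIndex", function(x) standardGeneric("overallIndex"))

#' @rdname overallIndex
#' @aliases overallIndex,ProximityResult-method
setMethod("overallIndex", "ProximityResult", function(x) x@proximityIndex)

#' Per-window proximity indices
#' @param x a [ProximityResult-class].
#' @return matrix of per-window indices (rows = vertical window origins).
#' @export
setGeneric("perWindowIndex", function(x) standardGeneric("perWindowIndex"))

#' @rdname perWindowIndex
#' @aliases perWindowIndex,ProximityResult-method
setMethod("perWindowIndex", "ProximityResult", function(x) x@perWindowIndex)

#' Number of windows with a non-zero index
#' @param x a [ProximityResult-class].
#' @return window count.
#' @export
setGeneric("nNonzeroWindows", function(x) standardGeneric("nNonzeroWindows"))

#' @rdname nNonzeroWindows
#' @aliases nNonzeroWindows,ProximityResult-method
setMethod("nNonzeroWindows", "ProximityResult", function(x) x@nNonzeroWindows)

#' Selected window exponent of a sweep
#' @param x a [SweepResult-class].
#' @return integer k maximising group separation.
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname selectedK
#' @aliases selectedK,SweepResult-method
setMethod("selectedK", "SweepResult", function(x) x@selectedK)

#' Per-k group separation of a sweep
#' @param x a [SweepResult-class].
#' @return named numeric vector, one entry per k.
#' @export
setGeneric("separation", function(x) standardGeneric("separation"))

#' @rdname separation
#' @aliases separation,SweepResult-method
setMethod("separation", "SweepResult", function(x) x@separation)

#' Per-k, per-group mean proximity table of a sweep
#' @param x a [SweepResult-class].
#' @return data.frame with columns k, group, mean_proximity.
#' @export
setGeneric("perKGroupMeans", function(x) standardGeneric("perKGroupMeans"))

#' @rdname perKGroupMeans
#' @aliases perKGroupMeans,SweepResult-method
setMethod("perKGroupMeans", "SweepResult", function(x) x@perKGroupMeans)

#' Scene accessors
#' @param x a [SyntheticScene-class].
#' @return the rendered image, a truth mask, or the generating config.
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname sceneImage
#' @aliases sceneImage,SyntheticScene-method
setMethod("sceneImage", "SyntheticScene", function(x) x@image)

#' @rdname sceneImage
#' @export
setGeneric("truthMitoMask", function(x) standardGeneric("truthMitoMask"))

#' @rdname sceneImage
#' @aliases truthMitoMask,SyntheticScene-method
setMethod("truthMitoMask", "SyntheticScene", function(x) x@truthMitoMask)

#' @rdname sceneImage
#' @export
setGeneric("truthProteinMask", function(x) standardGeneric("truthProteinMask"))

#' @rdname sceneImage
#' @aliases truthProteinMask,SyntheticScene-method
setMethod("truthProteinMask", "SyntheticScene", function(x) x@truthProteinMask)

#' @rdname sceneImage
#' @export
setGeneric("sceneConfig", function(x) standardGeneric("sceneConfig"))

#' @rdname sceneImage
#' @aliases sceneConfig,SyntheticScene-method
setMethod("sceneConfig", "SyntheticScene", function(x) x@config)

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat("MultiChannelImage:", d[1L], "x", d[2L], "px,",
      length(object@pixels), "channel(s) [",
      paste(names(object@pixels), collapse = ", "), "], bit depth",
      object@bitDepth, "\n")
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@pixels)
  cat("BinaryMask:", d[1L], "x", d[2L], "px,",
      sum(object@pixels), "foreground px")
  if (!is.na(object@sourceChannel))
    cat(", channel '", object@sourceChannel, "'", sep = "")
  if (!is.na(object@threshold))
    cat(", threshold ", signif(object@threshold, 5), sep = "")
  cat("\n")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult: common", object@common, "/ union", object@union,
      "=", signif(object@overlap, 5),
      sprintf("(%.2f%%)\n", object@overlapPercent))
})

setMethod("show", "ProximityResult", function(object) {
  cat("ProximityResult: window", windowSize(object), "px (k =",
      object@config@k, "), index", signif(object@proximityIndex, 5),
      "over", object@nNonzeroWindows, "non-zero window(s) of",
      length(object@perWindowIndex), "\n")
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult: selected k =", object@selectedK,
      "(window", 2L^object@selectedK, "px), separation",
      signif(object@separation[as.character(object@selectedK)], 5), "\n")
})

setMethod("show", "SyntheticScene", function(object) {
  cfg <- object@config
  cat("SyntheticScene:", cfg@height, "x", cfg@width, "px,",
      cfg@phenotype, "/", cfg@proteinMode,
      "(coloc", cfg@colocFraction, ", shift", cfg@displacement,
      "px, seed", cfg@seed, ")\n")
})
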