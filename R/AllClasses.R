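#' @import methods
NULL

#' Multi-channel 2D intensity image
#'
#' Container for a single-plane, multi-channel fluorescence image. Each
#' channel is a numeric matrix of non-negative intensities on its native
#' scale (no normalisation is applied on read), indexed row-major with the
#' origin at the top-left corner.
#'
#' @slot pixels named list of numeric matrices, one per channel; all
#'   channels share the same height and width.
#' @slot bitDepth character, one of \code{"8"}, \code{"16"} or
#'   \code{"float"}; records the sample format of the source file.
#'
#' @seealso [readMultiChannelImage()], [extractPair()]
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(pixels = "list", bitDepth = "character"),
  prototype(pixels = list(), bitDepth = "float"))

setValidity("MultiChannelImage", function(object) {
  px <- object@pixels
  if (length(px) < 1L)
    return("at least one channel is required")
  if (is.null(names(px)) || anyDuplicated(names(px)) || any(!nzchar(names(px))))
    return("channels must have unique non-empty names")
  if (!all(vapply(px, is.matrix, logical(1))))
    return("every channel must be a 2D matrix")
  d <- dim(px[[1L]])
  for (ch in px) {
    if (!identical(dim(ch), d))
      return("all channels must share the same height x width")
    if (any(!is.finite(ch)) || any(ch < 0))
      return("intensities must be finite and non-negative")
  }
  if (!object@bitDepth %in% c("8", "16", "float"))
    return("bitDepth must be one of '8', '16', 'float'")
  TRUE
})

#' Construct a MultiChannelImage
#'
#' @param pixels list of numeric matrices (one per channel), or a single
#'   matrix for a one-channel image.
#' @param channelNames optional character vector of channel labels; defaults
#'   to the names of \code{pixels} or \code{"ch1"}, \code{"ch2"}, ...
#' @param bitDepth \code{"8"}, \code{"16"} or \code{"float"}.
#' @return A [MultiChannelImage-class] object.
#' @examples
#' img <- MultiChannelImage(list(mito = matrix(0, 8, 8),
#'                               protein = matrix(1, 8, 8)))
#' channelNames(img)
#' @export
MultiChannelImage <- function(pixels, channelNames = NULL, bitDepth = "float") {
  if (is.matrix(pixels)) pixels <- list(pixels)
  if (length(pixels) == 0L)
    stop("at least one channel is required", call. = FALSE)
  pixels <- lapply(pixels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  if (!is.null(channelNames)) {
    if (length(channelNames) != length(pixels))
      stop("configuration error: ", length(channelNames), " channel name(s) ",
           "supplied for ", length(pixels), " plane(s)", call. = FALSE)
    names(pixels) <- channelNames
  } else if (is.null(names(pixels))) {
    names(pixels) <- paste0("ch", seq_along(pixels))
  }
  new("MultiChannelImage", pixels = pixels, bitDepth = bitDepth)
}

#' Region-of-interest mask
#'
#' Boolean grid restricting the analysis to part of a field, e.g. a single
#' cell. Pixels outside the ROI are zeroed before thresholding.
#'
#' @slot pixels logical matrix, TRUE inside the ROI.
#' @slot label free-text label for the region.
#' @exportClass RoiMask
setClass("RoiMask",
  representation(pixels = "matrix", label = "character"),
  prototype(label = "roi"))

setValidity("RoiMask", function(object) {
  if (!is.logical(object@pixels))
    return("ROI pixels must be logical")
  if (!any(object@pixels))
    return("ROI must contain at least one TRUE pixel")
  TRUE
})

#' Construct an RoiMask
#'
#' @param pixels logical (or coercible) matrix; nonzero means inside.
#' @param label free-text label.
#' @return An [RoiMask-class] object.
#' @export
RoiMask <- function(pixels, label = "roi") {
  m <- pixels
  if (!is.logical(m)) {
    m2 <- m != 0
    dim(m2) <- dim(m)
    m <- m2
  }
  new("RoiMask", pixels = m, label = label)
}

#' Binary segmentation mask
#'
#' The result of thresholding one channel: 1 marks segmented foreground
#' (mitochondria or protein), 0 marks background. The threshold that was
#' actually applied is stored for reproducibility.
#'
#' @slot pixels numeric matrix over {0, 1}.
#' @slot sourceChannel label of the channel the mask was derived from.
#' @slot threshold realized intensity threshold (NA when not applicable,
#'   e.g. a hand-built mask or a degenerate constant channel).
#' @seealso [thresholdChannel()], [percentOverlap()], [proximityIndex()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", sourceChannel = "character",
                 threshold = "numeric"),
  prototype(sourceChannel = NA_character_, threshold = NA_real_))

setValidity("BinaryMask", function(object) {
  px <- object@pixels
  if (!is.numeric(px))
    return("mask pixels must be numeric")
  if (!all(px %in% c(0, 1)))
    return("mask pixels must be exactly 0 or 1")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param pixels matrix of 0/1 (logical matrices are converted).
#' @param sourceChannel label of the originating channel.
#' @param threshold realized threshold, if any.
#' @return A [BinaryMask-class] object.
#' @examples
#' m <- BinaryMask(matrix(c(0, 1, 1, 0), 2, 2))
#' sum(maskPixels(m))
#' @export
BinaryMask <- function(pixels, sourceChannel = NA_character_,
                       threshold = NA_real_) {
  m <- pixels
  storage.mode(m) <- "double"
  new("BinaryMask", pixels = m, sourceChannel = sourceChannel,
      threshold = threshold)
}

#' Preprocessing parameters
#'
#' Controls the denoising applied to a channel before thresholding: a
#' median filter (square window of side 2*medianRadius + 1) followed by a
#' white top-hat with a disc structuring element of radius tophatRadius.
#' Either stage can be disabled, in which case it is the identity.
#'
#' @slot medianRadius integer radius in pixels (window side 2r+1).
#' @slot tophatRadius integer disc radius in pixels.
#' @slot medianEnabled,tophatEnabled logical flags.
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(medianRadius = "integer", tophatRadius = "integer",
                 medianEnabled = "logical", tophatEnabled = "logical"))

setValidity("PreprocessParams", function(object) {
  if (object@medianEnabled && object@medianRadius < 1L)
    return("medianRadius must be >= 1 when the median filter is enabled")
  if (object@tophatEnabled && object@tophatRadius < 1L)
    return("tophatRadius must be >= 1 when the top-hat filter is enabled")
  TRUE
})

#' Construct PreprocessParams
#'
#' Defaults (3x3 median, disc-15 top-hat) suit tubular organelles imaged at
#' roughly 100 nm per pixel; both radii are freely configurable.
#'
#' @param medianRadius median window radius in pixels.
#' @param tophatRadius top-hat disc radius in pixels.
#' @param medianEnabled,tophatEnabled enable/disable each stage.
#' @return A [PreprocessParams-class] object.
#' @export
PreprocessParams <- function(medianRadius = 1L, tophatRadius = 15L,
                             medianEnabled = TRUE, tophatEnabled = TRUE) {
  new("PreprocessParams",
      medianRadius = as.integer(medianRadius),
      tophatRadius = as.integer(tophatRadius),
      medianEnabled = medianEnabled, tophatEnabled = tophatEnabled)
}

#' Threshold specification
#'
#' @slot method \code{"otsu"}, \code{"fixed"} or \code{"quantile"}.
#' @slot level fixed intensity threshold (method \code{"fixed"}) or
#'   upper-tail foreground fraction in (0, 1) (method \code{"quantile"});
#'   ignored for Otsu.
#' @exportClass ThresholdSpec
setClass("ThresholdSpec",
  representation(method = "character", level = "numeric"),
  prototype(method = "otsu", level = NA_real_))

setValidity("ThresholdSpec", function(object) {
  if (!object@method %in% c("otsu", "fixed", "quantile"))
    return("method must be 'otsu', 'fixed' or 'quantile'")
  if (object@method == "fixed" && !is.finite(object@level))
    return("a finite level is required for method 'fixed'")
  if (object@method == "quantile" &&
      (!is.finite(object@level) || object@level <= 0 || object@level >= 1))
    return("quantile level must lie in (0, 1)")
  TRUE
})

#' Construct a ThresholdSpec
#'
#' @param method \code{"otsu"} (default), \code{"fixed"} or \code{"quantile"}.
#' @param level see [ThresholdSpec-class].
#' @return A [ThresholdSpec-class] object.
#' @export
ThresholdSpec <- function(method = "otsu", level = NA_real_) {
  new("ThresholdSpec", method = method, level = as.numeric(level))
}

#' Overlap statistic result
#'
#' Percent overlap of two binary masks: the number of pixels foreground in
#' both (logical AND) divided by the number foreground in either (logical
#' OR). 1 means complete overlap, 0 means none.
#'
#' @slot common AND pixel count.
#' @slot union OR pixel count.
#' @slot overlap fraction in [0, 1] (defined 0 when the union is empty).
#' @slot overlapPercent 100 * overlap.
#' @seealso [percentOverlap()]
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(common = "numeric", union = "numeric",
                 overlap = "numeric", overlapPercent = "numeric"))

#' Sliding-window configuration for the proximity index
#'
#' Windows are 2^k x 2^k pixels, swept from the top-left to the
#' bottom-right of the averaged image. The default stride equals the window
#' size (non-overlapping tiling), so the window count in the final
#' denominator is unambiguous.
#'
#' @slot k window exponent, integer in [2, 10].
#' @slot stride step between window origins, in pixels.
#' @slot edgePolicy \code{"partial"} (truncated edge windows kept, default),
#'   \code{"pad"} (zero-pad to full windows) or \code{"drop"} (discard
#'   incomplete windows).
#' @exportClass ProximityConfig
setClass("ProximityConfig",
  representation(k = "integer", stride = "integer", edgePolicy = "character"))

setValidity("ProximityConfig", function(object) {
  if (object@k < 2L || object@k > 10L)
    return("k must be an integer in [2, 10]")
  if (object@stride < 1L)
    return("stride must be >= 1")
  if (!object@edgePolicy %in% c("partial", "pad", "drop"))
    return("edgePolicy must be 'partial', 'pad' or 'drop'")
  TRUE
})

#' Construct a ProximityConfig
#'
#' @param k window exponent; the window is 2^k pixels per side. The default
#'   k = 6 (window 64) is the granularity used for the mitochondria/Ral
#'   analyses.
#' @param stride window step in pixels; defaults to the window size
#'   (non-overlapping tiling).
#' @param edgePolicy how to treat windows extending past the image edge.
#' @return A [ProximityConfig-class] object.
#' @examples
#' windowSize(ProximityConfig(k = 6))
#' @export
ProximityConfig <- function(k = 6L, stride = NULL,
                            edgePolicy = c("partial", "pad", "drop")) {
  k <- as.integer(k)
  if (is.null(stride)) stride <- 2L^k
  new("ProximityConfig", k = k, stride = as.integer(stride),
      edgePolicy = match.arg(edgePolicy))
}

#' Proximity index result
#'
#' @slot perWindowIndex matrix of per-window indices in [0, 1], one entry
#'   per window position (rows index vertical window origins).
#' @slot nNonzeroWindows number of windows with a non-zero index.
#' @slot proximityIndex overall index: sum of per-window indices divided by
#'   the number of non-zero windows (0 if none).
#' @slot config the [ProximityConfig-class] used.
#' @seealso [proximityIndex()]
#' @exportClass ProximityResult
setClass("ProximityResult",
  representation(perWindowIndex = "matrix", nNonzeroWindows = "integer",
                 proximityIndex = "numeric", config = "ProximityConfig"))

#' Window-size sweep result
#'
#' @slot perKGroupMeans data.frame with columns \code{k}, \code{group},
#'   \code{mean_proximity}.
#' @slot separation named numeric vector: for each k, the largest absolute
#'   difference between two group means.
#' @slot selectedK the k maximising the separation (ties broken toward the
#'   smaller k).
#' @seealso [windowSizeSweep()]
#' @exportClass SweepResult
setClass("SweepResult",
  representation(perKGroupMeans = "data.frame", separation = "numeric",
                 selectedK = "integer"))

#' Synthetic scene configuration
#'
#' Ground-truth parameters for a rendered two-channel scene: a mitochondria
#' channel (tubular network or fragmented perinuclear clusters) and a
#' protein channel drawn in one of several spatial relationships to it,
#' blurred by a Gaussian PSF and degraded by a linear background gradient
#' plus Poisson-like shot noise and Gaussian read noise.
#'
#' @slot height,width image size in pixels (both >= 64 so the window-64
#'   statistic is usable).
#' @slot phenotype \code{"network"} or \code{"fragmented_perinuclear"}.
#' @slot proteinMode \code{"membrane"}, \code{"cytosolic_puncta"},
#'   \code{"mito_colocalized"}, \code{"mito_ring"} or
#'   \code{"mito_adjacent_puncta"}.
#' @slot colocFraction fraction in [0, 1] of the protein signal placed on
#'   mitochondria (mode \code{"mito_colocalized"}).
#' @slot displacement horizontal toroidal shift of the protein pattern, px.
#' @slot nTubules,nFragments structure counts for the two phenotypes.
#' @slot psfSigma Gaussian PSF sigma in pixels.
#' @slot backgroundGradientAmplitude peak of the linear background ramp,
#'   intensity units.
#' @slot noiseScale noise gain; 0 disables all noise.
#' @slot seed RNG seed making the scene reproducible.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(height = "integer", width = "integer",
                 phenotype = "character", proteinMode = "character",
                 colocFraction = "numeric", displacement = "numeric",
                 nTubules = "integer", nFragments = "integer",
                 psfSigma = "numeric",
                 backgroundGradientAmplitude = "numeric",
                 noiseScale = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@height < 64L || object@width < 64L)
    return("scene dimensions must be >= 64 pixels")
  if (!object@phenotype %in% c("network", "fragmented_perinuclear"))
    return(paste0("unknown phenotype '", object@phenotype, "'"))
  modes <- c("membrane", "cytosolic_puncta", "mito_colocalized",
             "mito_ring", "mito_adjacent_puncta")
  if (!object@proteinMode %in% modes)
    return(paste0("unknown proteinMode '", object@proteinMode, "'"))
  if (object@colocFraction < 0 || object@colocFraction > 1)
    return("colocFraction must lie in [0, 1]")
  if (object@displacement < 0)
    return("displacement must be >= 0")
  if (object@psfSigma < 0 || object@noiseScale < 0 ||
      object@backgroundGradientAmplitude < 0)
    return("psfSigma, noise and background amplitudes must be >= 0")
  TRUE
})

#' Construct a SceneConfig
#'
#' Defaults emulate a depolarization-style field: a 256 x 256 px crop of a
#' cell with a dense tubular mitochondrial network, the protein fully
#' recruited onto it, a modest linear background and confocal-like noise.
#' The field is four 64-px windows on a side, so the window-64 statistic
#' averages over a 4 x 4 tiling.
#'
#' @param height,width image size in pixels.
#' @param phenotype mitochondrial morphology; see [SceneConfig-class].
#' @param proteinMode protein spatial pattern; see [SceneConfig-class].
#' @param colocFraction fraction of protein signal on mitochondria.
#' @param displacement horizontal toroidal shift of the protein pattern.
#' @param nTubules,nFragments structure counts.
#' @param psfSigma PSF sigma in pixels.
#' @param backgroundGradientAmplitude background ramp peak.
#' @param noiseScale noise gain (0 = noiseless).
#' @param seed RNG seed.
#' @return A [SceneConfig-class] object.
#' @export
SceneConfig <- function(height = 256L, width = 256L,
                        phenotype = "network",
                        proteinMode = "mito_colocalized",
                        colocFraction = 1, displacement = 0,
                        nTubules = 24L, nFragments = 30L,
                        psfSigma = 1, backgroundGradientAmplitude = 20,
                        noiseScale = 5, seed = 1L) {
  new("SceneConfig",
      height = as.integer(height), width = as.integer(width),
      phenotype = phenotype, proteinMode = proteinMode,
      colocFraction = as.numeric(colocFraction),
      displacement = as.numeric(displacement),
      nTubules = as.integer(nTubules), nFragments = as.integer(nFragments),
      psfSigma = as.numeric(psfSigma),
      backgroundGradientAmplitude = as.numeric(backgroundGradientAmplitude),
      noiseScale = as.numeric(noiseScale), seed = as.integer(seed))
}

#' Rendered synthetic scene with ground truth
#'
#' @slot image the rendered two-channel [MultiChannelImage-class]
#'   (channels \code{"mito"} and \code{"protein"}).
#' @slot truthMitoMask,truthProteinMask the pre-blur, pre-noise binary
#'   patterns the channels were rendered from.
#' @slot config the generating [SceneConfig-class].
#' @seealso [generateScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(image = "MultiChannelImage",
                 truthMitoMask = "BinaryMask",
                 truthProteinMask = "BinaryMask",
                 config = "SceneConfig"))

setValidity("SyntheticScene", function(object) {
  d <- dim(object@image@pixels[[1L]])
  if (!identical(dim(object@truthMitoMask@pixels), d) ||
      !identical(dim(object@truthProteinMask@pixels), d))
    return("truth masks must match the image shape")
  TRUE
})
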