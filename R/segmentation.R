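.asImageMatrix <- function(x) {
  m <- if (is(x, "Image")) EBImage::imageData(x) else x
  if (!is.matrix(m) || !is.numeric(m))
    stop("input error: channel must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop("input error: channel contains non-finite values", call. = FALSE)
  m
}

#' Denoise and background-correct a channel
#'
#' Applies the preprocessing used before segmentation: a median filter
#' (noise removal) followed by a white top-hat (image minus its
#' morphological opening with a disc), which suppresses slowly varying
#' background while keeping features narrower than the disc. Disabled
#' stages are the identity. Adding a constant offset to the whole image
#' does not change the top-hat output.
#'
#' The median filter runs on a rescaled copy of the channel (its backend
#' quantises to 2^16 levels of the channel range), so values may move by up
#' to \code{max(channel) / 65535}; this is far below any useful threshold.
#'
#' @param channel numeric matrix of finite, non-negative intensities.
#' @param params a [PreprocessParams-class].
#' @return The filtered intensity matrix (non-negative).
#' @export
preprocessChannel <- function(channel, params = PreprocessParams()) {
  stopifnot(is(params, "PreprocessParams"))
  m <- .asImageMatrix(channel)
  if (any(m < 0))
    stop("input error: intensities must be non-negative", call. = FALSE)
  d <- dim(m)

  if (params@medianEnabled) {
    side <- 2L * params@medianRadius + 1L
    if (side > min(d))
      stop("configuration error: median window (", side,
           " px) exceeds the image", call. = FALSE)
    mx <- max(m)
    if (mx > 0) {
      filtered <- EBImage::medianFilter(m / mx, params@medianRadius)
      m <- EBImage::imageData(filtered) * mx
      dim(m) <- d
    }
  }

  if (params@tophatEnabled) {
    side <- 2L * params@tophatRadius + 1L
    if (side > min(d))
      stop("configuration error: top-hat disc (", side,
           " px) exceeds the image", call. = FALSE)
    kern <- EBImage::makeBrush(side, shape = "disc")
    mx <- max(m)
    if (mx > 0) {
      # the morphology backend operates on [0,1]; grayscale opening
      # commutes with positive scaling, so rescale around it
      m <- EBImage::imageData(EBImage::whiteTopHat(m / mx, kern)) * mx
      dim(m) <- d
    }
  }

  pmax(m, 0)
}

.otsuThreshold <- function(m) {
  rng <- range(m)
  EBImage::otsu(EBImage::Image(m), range = rng, levels = 256L)
}

#' Threshold a channel into a binary mask
#'
#' Simple global thresholding: a pixel is foreground (1) iff its intensity
#' strictly exceeds the threshold. Levels can be chosen automatically by
#' Otsu's method (default, a reproducible surrogate for choosing a level
#' that removes the noisy background), fixed at a given intensity, or set
#' at an upper-tail quantile. The realized threshold is stored on the
#' returned mask so every segmentation can be reconstructed.
#'
#' @param channel numeric matrix of finite intensities.
#' @param spec a [ThresholdSpec-class].
#' @param sourceChannel label recorded on the mask.
#' @return A [BinaryMask-class]. A constant channel under Otsu yields an
#'   all-zero mask with a warning (degenerate histogram).
#' @export
thresholdChannel <- function(channel, spec = ThresholdSpec(),
                             sourceChannel = NA_character_) {
  stopifnot(is(spec, "ThresholdSpec"))
  m <- .asImageMatrix(channel)
  thr <- switch(spec@method,
    otsu = {
      if (diff(range(m)) == 0) {
        warning("constant channel: Otsu threshold is undefined; ",
                "returning an empty mask", call. = FALSE)
        NA_real_
      } else {
        .otsuThreshold(m)
      }
    },
    fixed = spec@level,
    quantile = stats::quantile(m, 1 - spec@level, names = FALSE))
  px <- if (is.na(thr)) matrix(0, nrow(m), ncol(m)) else (m > thr) * 1
  BinaryMask(px, sourceChannel = sourceChannel, threshold = thr)
}

#' Segment a channel pair
#'
#' Runs [preprocessChannel()] then [thresholdChannel()] independently on
#' two named channels of an image. If an ROI is supplied, pixels outside it
#' are zeroed after filtering and before thresholding, restricting the
#' analysis to e.g. a single cell.
#'
#' @param img a [MultiChannelImage-class].
#' @param chanA,chanB channel labels (typically mitochondria and protein).
#' @param params a [PreprocessParams-class] applied to both channels.
#' @param specA,specB per-channel [ThresholdSpec-class]s (\code{specB}
#'   defaults to \code{specA}).
#' @param roi optional [RoiMask-class] of the same shape as the image.
#' @return A named list of two [BinaryMask-class]s, in request order.
#' @export
segmentPair <- function(img, chanA, chanB, params = PreprocessParams(),
                        specA = ThresholdSpec(), specB = specA, roi = NULL) {
  pair <- extractPair(img, chanA, chanB)
  if (!is.null(roi)) {
    stopifnot(is(roi, "RoiMask"))
    if (!identical(dim(roi@pixels), dim(img)))
      stop("input error: ROI shape does not match the image", call. = FALSE)
  }
  segOne <- function(channel, spec, label) {
    f <- preprocessChannel(channel, params)
    if (!is.null(roi)) f[!roi@pixels] <- 0
    thresholdChannel(f, spec, sourceChannel = label)
  }
  out <- list(segOne(pair[[1L]], specA, chanA),
              segOne(pair[[2L]], specB, chanB))
  names(out) <- c(chanA, chanB)
  out
}
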