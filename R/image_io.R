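#' Read a multi-channel TIFF image
#'
#' Reads a multi-page (one channel per plane) or interleaved-RGB TIFF and
#' returns every plane as a channel. Integer samples are read on their
#' native scale (0..2^bits - 1) without normalisation, so downstream
#' thresholds operate on raw filtered intensity. An RGB plane is split into
#' three channels in R, G, B order.
#'
#' @param path path to a TIFF / OME-TIFF file.
#' @param channelNames optional labels, one per resulting channel.
#' @return A [MultiChannelImage-class].
#' @examples
#' f <- tempfile(fileext = ".tif")
#' img <- MultiChannelImage(list(mito = matrix(3, 4, 4),
#'                               protein = matrix(7, 4, 4)), bitDepth = "16")
#' writeMultiChannelImage(img, f)
#' readMultiChannelImage(f, c("mito", "protein"))
#' @export
readMultiChannelImage <- function(path, channelNames = NULL) {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  planes <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e)
      stop("format error: cannot read TIFF '", path, "': ",
           conditionMessage(e), call. = FALSE))
  if (length(planes) < 1L)
    stop("format error: no image planes in ", path, call. = FALSE)

  bits <- attr(planes[[1L]], "bits.per.sample")
  fmt <- attr(planes[[1L]], "sample.format")
  bitDepth <- if (!is.null(fmt) && identical(fmt, "float")) "float"
              else if (identical(bits, 8L)) "8"
              else if (identical(bits, 16L)) "16"
              else "float"

  channels <- list()
  for (p in planes) {
    a <- p
    attributes(a) <- attributes(a)["dim"]
    if (length(dim(a)) == 3L) {
      # interleaved RGB comes back normalised to [0,1] regardless of
      # as.is; restore the native integer scale
      top <- if (bitDepth == "float") 1 else 2^as.integer(bitDepth) - 1
      for (j in seq_len(dim(a)[3L])) {
        ch <- a[, , j] * top
        if (bitDepth != "float") ch <- round(ch)
        channels[[length(channels) + 1L]] <- ch
      }
    } else {
      channels[[length(channels) + 1L]] <- a
    }
  }
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  MultiChannelImage(channels, channelNames = channelNames,
                    bitDepth = bitDepth)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Integer bit depths round-trip exactly through
#' [readMultiChannelImage()]; one plane is written per channel.
#'
#' @param x a [MultiChannelImage-class].
#' @param path output path.
#' @param bitDepth override the image's stored bit depth ("8", "16" or
#'   "float").
#' @return \code{path}, invisibly.
#' @export
writeMultiChannelImage <- function(x, path, bitDepth = NULL) {
  stopifnot(is(x, "MultiChannelImage"))
  bd <- if (is.null(bitDepth)) x@bitDepth else bitDepth
  if (bd == "float") {
    # float TIFF samples must sit in [0,1]; scale by a power of two so the
    # division is exact in binary floating point
    mx <- max(1, vapply(x@pixels, max, numeric(1)))
    sc <- 2^ceiling(log2(mx))
    planes <- lapply(x@pixels, function(m) m / sc)
    tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    bits <- as.integer(bd)
    top <- 2^bits - 1
    planes <- lapply(x@pixels, function(m) {
      if (max(m) > top)
        stop("intensities exceed the ", bits, "-bit range", call. = FALSE)
      round(m) / top
    })
    tiff::writeTIFF(planes, path, bits.per.sample = bits, reduce = FALSE)
  }
  invisible(path)
}

#' Read a region-of-interest mask
#'
#' Accepts a single-plane TIFF or a PNG; any nonzero pixel is inside the
#' ROI.
#'
#' @param path path to the mask file.
#' @param label free-text label attached to the ROI.
#' @return An [RoiMask-class].
#' @export
readRoiMask <- function(path, label = "roi") {
  if (!file.exists(path))
    stop("format error: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    png::readPNG(path)
  } else {
    tryCatch(tiff::readTIFF(path, as.is = TRUE),
             error = function(e)
               stop("format error: cannot read ROI '", path, "': ",
                    conditionMessage(e), call. = FALSE))
  }
  a <- m
  attributes(a) <- attributes(a)["dim"]
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  RoiMask(a != 0, label = label)
}

#' Extract a pair of channels
#'
#' Pure projection: returns the two named channels, unchanged, in the
#' requested order.
#'
#' @param img a [MultiChannelImage-class].
#' @param chanA,chanB channel labels.
#' @return A list of two intensity matrices named after the channels.
#' @export
extractPair <- function(img, chanA, chanB) {
  stopifnot(is(img, "MultiChannelImage"))
  out <- list(getChannel(img, chanA), getChannel(img, chanB))
  names(out) <- c(chanA, chanB)
  out
}
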