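.asMaskMatrix <- function(x, arg = "mask") {
  m <- if (is(x, "BinaryMask")) x@pixels else x
  if (is.logical(m)) {
    storage.mode(m) <- "double"
  }
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop("input error: ", arg, " must be a binary (0/1) matrix or BinaryMask",
         call. = FALSE)
  m
}

.checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("input error: masks differ in shape (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
}

#' Percent overlap of two binary masks
#'
#' The overlap statistic is the number of pixels foreground in both masks
#' (logical AND) divided by the number foreground in either (logical OR) —
#' the Jaccard index of the two segmentations. It equals 1 for complete
#' overlap and 0 for none; multiplied by 100 it is reported as percent
#' overlap. When both masks are empty the union is 0 and the overlap is
#' defined as 0, with a warning.
#'
#' @param maskA,maskB [BinaryMask-class] objects or 0/1 matrices of the
#'   same shape.
#' @return An [OverlapResult-class].
#' @examples
#' a <- matrix(0, 8, 8); a[2:3, 2:3] <- 1
#' b <- matrix(0, 8, 8); b[3:4, 2:3] <- 1
#' overlapFraction(percentOverlap(a, b))
#' @export
percentOverlap <- function(maskA, maskB) {
  a <- .asMaskMatrix(maskA, "maskA")
  b <- .asMaskMatrix(maskB, "maskB")
  .checkSameShape(a, b)
  common <- sum(a == 1 & b == 1)
  un <- sum(a == 1 | b == 1)
  if (un == 0) {
    warning("both masks are empty; overlap defined as 0", call. = FALSE)
    ov <- 0
  } else {
    ov <- common / un
  }
  new("OverlapResult", common = as.numeric(common), union = as.numeric(un),
      overlap = ov, overlapPercent = 100 * ov)
}

#' Per-pixel average of two binary masks
#'
#' First step of the proximity index: pixels where both structures exist
#' average to 1, pixels where exactly one exists average to 0.5, and empty
#' pixels stay 0.
#'
#' @param maskA,maskB [BinaryMask-class] objects or 0/1 matrices of the
#'   same shape.
#' @return A numeric matrix over \{0, 0.5, 1\}.
#' @export
averageMasks <- function(maskA, maskB) {
  a <- .asMaskMatrix(maskA, "maskA")
  b <- .asMaskMatrix(maskB, "maskB")
  .checkSameShape(a, b)
  (a + b) / 2
}

#' Ratio factor of a window
#'
#' For one window, the ratio of the first channel's foreground pixel count
#' to the second's and vice versa are formed; the minimum of the two, a
#' value in [0, 1], is the window's ratio factor. If either channel is
#' absent from the window the factor is 0, so the window contributes
#' nothing (matching the convention that absence of one channel gives a
#' zero index).
#'
#' @param countA,countB non-negative foreground pixel counts (vectorised).
#' @return ratio factor(s) in [0, 1].
#' @examples
#' windowRatioFactor(4, 2)  # 0.5
#' windowRatioFactor(5, 0)  # 0
#' @export
windowRatioFactor <- function(countA, countB) {
  if (any(countA < 0) || any(countB < 0))
    stop("input error: counts must be non-negative", call. = FALSE)
  ifelse(countA > 0 & countB > 0,
         pmin(countA / countB, countB / countA), 0)
}

#' Proximity index of a single window
#'
#' Every pixel of the averaged window is multiplied by the window's ratio
#' factor; the mean of the weighted pixels that are non-zero is the
#' window's proximity index (0 if there are none).
#'
#' @param avgWindow averaged-mask window, values in \{0, 0.5, 1\}.
#' @param ratio the window's ratio factor in [0, 1].
#' @return window index in [0, 1].
#' @examples
#' w <- matrix(0, 4, 4); w[1, 1:2] <- 1; w[2, 1:2] <- 0.5
#' windowProximity(w, 0.5)  # 0.375
#' @export
windowProximity <- function(avgWindow, ratio) {
  stopifnot(ratio >= 0, ratio <= 1)
  weighted <- avgWindow * ratio
  nz <- weighted > 0
  if (!any(nz)) return(0)
  mean(weighted[nz])
}

.windowStarts <- function(extent, win, stride, edgePolicy) {
  starts <- seq.int(1L, extent, by = stride)
  if (edgePolicy == "drop")
    starts <- starts[starts + win - 1L <= extent]
  starts
}

# summed-area table with a zero guard row/column, so that
# block sums reduce to four lookups
.sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

.blockSum <- function(s, i0, i1, j0, j1) {
  s[i1 + 1L, j1 + 1L] - s[i0, j1 + 1L] - s[i1 + 1L, j0] + s[i0, j0]
}

#' Sliding-window proximity index of two masks
#'
#' Captures the similarity of two spatial distributions even when the
#' structures are adjacent rather than coincident. The thresholded
#' channels are averaged per pixel (1 both, 0.5 one, 0 neither) and a
#' 2^k x 2^k window sweeps the averaged image from the top left to the
#' bottom right. In each window, the minimum of the two foreground count
#' ratios (the ratio factor) weights every pixel, and the mean of the
#' non-zero weighted pixels is that window's index. The overall index is
#' the sum of the window indices divided by the number of windows with a
#' non-zero index; 1 means completely overlapping structures, 0 means no
#' similarity or a channel absent everywhere.
#'
#' Windows are non-overlapping by default (stride = window size). Per-window
#' quantities are computed from summed-area tables of the two masks and
#' their union, which is algebraically identical to the per-pixel
#' definition: within a window with counts \eqn{c_A, c_B} the mean of the
#' non-zero averaged pixels is \eqn{(c_A + c_B) / (2 |A \cup B|)}.
#'
#' @param maskA,maskB [BinaryMask-class] objects or 0/1 matrices of the
#'   same shape; the statistic is symmetric in the two.
#' @param config a [ProximityConfig-class]; the default uses k = 6
#'   (window 64), the granularity adopted for the mitochondria/Ral
#'   analyses.
#' @return A [ProximityResult-class].
#' @examples
#' m <- matrix(0, 128, 128); m[40:80, 40:80] <- 1
#' overallIndex(proximityIndex(m, m))  # identical masks give 1
#' @export
proximityIndex <- function(maskA, maskB, config = ProximityConfig()) {
  stopifnot(is(config, "ProximityConfig"))
  a <- .asMaskMatrix(maskA, "maskA")
  b <- .asMaskMatrix(maskB, "maskB")
  .checkSameShape(a, b)
  win <- windowSize(config)
  d <- dim(a)
  if (win > min(d))
    stop("configuration error: window size ", win,
         " exceeds image extent ", paste(d, collapse = "x"), call. = FALSE)

  if (config@edgePolicy == "pad") {
    padTo <- function(extent) {
      nStarts <- length(seq.int(1L, extent, by = config@stride))
      max(extent, (nStarts - 1L) * config@stride + win)
    }
    H <- padTo(d[1L]); W <- padTo(d[2L])
    if (H > d[1L] || W > d[2L]) {
      a2 <- matrix(0, H, W); a2[seq_len(d[1L]), seq_len(d[2L])] <- a; a <- a2
      b2 <- matrix(0, H, W); b2[seq_len(d[1L]), seq_len(d[2L])] <- b; b <- b2
    }
    d <- c(H, W)
  }

  rows <- .windowStarts(d[1L], win, config@stride, config@edgePolicy)
  cols <- .windowStarts(d[2L], win, config@stride, config@edgePolicy)

  sA <- .sat(a)
  sB <- .sat(b)
  sU <- .sat((a + b - a * b))   # union indicator

  idx <- matrix(0, length(rows), length(cols))
  for (ii in seq_along(rows)) {
    i0 <- rows[ii]; i1 <- min(i0 + win - 1L, d[1L])
    for (jj in seq_along(cols)) {
      j0 <- cols[jj]; j1 <- min(j0 + win - 1L, d[2L])
      ca <- .blockSum(sA, i0, i1, j0, j1)
      cb <- .blockSum(sB, i0, i1, j0, j1)
      r <- windowRatioFactor(ca, cb)
      if (r > 0) {
        nOr <- .blockSum(sU, i0, i1, j0, j1)
        # mean over non-zero averaged pixels, then weighted by r
        idx[ii, jj] <- r * (ca + cb) / (2 * nOr)
      }
    }
  }
  nz <- sum(idx > 0)
  overall <- if (nz > 0) sum(idx) / nz else 0
  new("ProximityResult", perWindowIndex = idx, nNonzeroWindows = as.integer(nz),
      proximityIndex = overall, config = config)
}

#' Window-size sweep across treatment groups
#'
#' The overlap statistic is independent of window size, but the proximity
#' index is defined at the granularity of its window. Averaging the index
#' over the images of each treatment group at every window size
#' 2^k, k in \code{kRange}, identifies the size giving the widest
#' distinction between groups: the separation at each k is the largest
#' absolute difference between two group means, and the selected k
#' maximises it (ties broken toward the smaller window).
#'
#' @param groups named list (>= 2 entries) of per-group lists; each element
#'   of a group is a list of two masks \code{list(maskA, maskB)}.
#' @param kRange integer window exponents to scan (default 2:10); all
#'   masks must be at least 2^max(kRange) pixels on each side.
#' @param edgePolicy edge policy forwarded to [proximityIndex()].
#' @return A [SweepResult-class].
#' @export
windowSizeSweep <- function(groups, kRange = 2:10,
                            edgePolicy = c("partial", "pad", "drop")) {
  edgePolicy <- match.arg(edgePolicy)
  if (is.null(names(groups)) || length(groups) < 2L)
    stop("configuration error: at least two named groups are required",
         call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("configuration error: every group needs at least one mask pair",
         call. = FALSE)
  kRange <- sort(as.integer(kRange))

  tab <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(groups[[g]], function(pair) {
      vals <- vapply(kRange, function(k) {
        overallIndex(proximityIndex(pair[[1L]], pair[[2L]],
                                    ProximityConfig(k = k,
                                                    edgePolicy = edgePolicy)))
      }, numeric(1))
      data.frame(k = kRange, group = g, proximity = vals)
    }))
  }))

  means <- aggregate(proximity ~ k + group, tab, mean)
  names(means)[names(means) == "proximity"] <- "mean_proximity"
  means <- means[order(means$k, means$group), , drop = FALSE]
  rownames(means) <- NULL

  sep <- vapply(kRange, function(k) {
    v <- means$mean_proximity[means$k == k]
    max(dist(v))
  }, numeric(1))
  names(sep) <- kRange
  selected <- kRange[which.max(sep)]   # first max: smallest k wins ties

  new("SweepResult", perKGroupMeans = means, separation = sep,
      selectedK = as.integer(selected))
}
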