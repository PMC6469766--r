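# Independent reference implementations used as oracles. These follow the
# stepwise verbal definition of each statistic with plain loops and no code
# shared with the package internals.

random_mask <- function(H, W, p = 0.3) {
  matrix(stats::rbinom(H * W, 1, p), H, W)
}

# brute-force AND / OR pixel counting
brute_overlap <- function(A, B) {
  common <- 0L
  un <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] == 1 && B[i, j] == 1) common <- common + 1L
    if (A[i, j] == 1 || B[i, j] == 1) un <- un + 1L
  }
  list(common = common, union = un,
       overlap = if (un > 0) common / un else 0)
}

# naive window-by-window execution of the proximity-index definition:
# average the masks, sweep a 2^k window top-left to bottom-right, weight
# each window by the minimum count ratio, average the non-zero weighted
# pixels, then divide the summed window indices by the non-zero count
naive_proximity <- function(A, B, k, stride = 2^k,
                            edge = c("partial", "drop")) {
  edge <- match.arg(edge)
  w <- 2^k
  H <- nrow(A); W <- ncol(A)
  avg <- (A + B) / 2
  rs <- seq(1, H, by = stride)
  cs <- seq(1, W, by = stride)
  if (edge == "drop") {
    rs <- rs[rs + w - 1 <= H]
    cs <- cs[cs + w - 1 <= W]
  }
  idx <- numeric(0)
  for (i0 in rs) for (j0 in cs) {
    i1 <- min(i0 + w - 1, H); j1 <- min(j0 + w - 1, W)
    a <- A[i0:i1, j0:j1]; b <- B[i0:i1, j0:j1]
    av <- avg[i0:i1, j0:j1]
    ca <- sum(a); cb <- sum(b)
    r <- if (ca > 0 && cb > 0) min(ca / cb, cb / ca) else 0
    wgt <- av * r
    idx <- c(idx, if (any(wgt > 0)) mean(wgt[wgt > 0]) else 0)
  }
  nz <- sum(idx > 0)
  if (nz > 0) sum(idx) / nz else 0
}

jaccard <- function(a, b) sum(a == 1 & b == 1) / sum(a == 1 | b == 1)

# brute-force grayscale white top-hat (erosion then dilation with the given
# structuring element, subtracted from the image); NA where the opening
# would need values beyond the border
brute_tophat_interior <- function(m, kern) {
  H <- nrow(m); W <- ncol(m)
  radius <- (nrow(kern) - 1L) %/% 2L
  offs <- which(kern == 1, arr.ind = TRUE) - (radius + 1L)
  inside <- function(i, j, marg) i >= 1 + marg && i <= H - marg &&
    j >= 1 + marg && j <= W - marg
  ero <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!inside(i, j, radius)) next
    ero[i, j] <- min(m[cbind(i + offs[, 1], j + offs[, 2])])
  }
  open <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!inside(i, j, 2L * radius)) next
    open[i, j] <- max(ero[cbind(i + offs[, 1], j + offs[, 2])])
  }
  m - open
}

# brute-force Otsu: scan every candidate threshold, maximise the
# between-class variance of the split
brute_otsu_mask <- function(m) {
  vals <- sort(unique(as.numeric(m)))
  best <- -Inf; bestThr <- vals[1]
  for (thr in vals[-length(vals)]) {
    lo <- m[m <= thr]; hi <- m[m > thr]
    w0 <- length(lo) / length(m); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (bc > best) {
      best <- bc
      bestThr <- thr
    }
  }
  (m > bestThr) * 1
}

scene_pixel_hash <- function(scenes) {
  buf <- unlist(lapply(scenes, function(s) {
    img <- sceneImage(s)
    unlist(lapply(channelNames(img), function(ch) getChannel(img, ch)))
  }))
  sum(buf * seq_along(buf) %% 97)
}
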