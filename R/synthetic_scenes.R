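# Deterministic scene synthesis. All randomness is drawn from the config
# seed inside a local RNG scope, so the caller's RNG state is untouched and
# a fixed seed gives bit-identical scenes. The draw order is fixed
# (mitochondria first, then the full protein candidate sets) so that scenes
# differing only in colocFraction or displacement are coupled: the
# mitochondria, the permutation of candidate on-mito pixels and the puncta
# centres are identical, and the fraction/shift merely select from them.

.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

.ellipseMask <- function(H, W, cy, cx, ry, rx) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

.stampDiscs <- function(m, centers, radius) {
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    ys <- max(1L, cy - radius):min(H, cy + radius)
    xs <- max(1L, cx - radius):min(W, cx + radius)
    for (y in ys) for (x in xs)
      if ((y - cy)^2 + (x - cx)^2 <= radius^2) m[y, x] <- 1
  }
  m
}

.dilateBinary <- function(m, radius) {
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- EBImage::imageData(EBImage::dilate(m, kern))
  dim(out) <- dim(m)
  out
}

.randomPointInCell <- function(cell) {
  H <- nrow(cell); W <- ncol(cell)
  repeat {
    y <- sample.int(H, 1L)
    x <- sample.int(W, 1L)
    if (cell[y, x]) return(c(y, x))
  }
}

.drawNetwork <- function(cell, nTubules) {
  H <- nrow(cell); W <- ncol(cell)
  marks <- matrix(0, H, W)
  len <- round(0.6 * min(H, W))
  for (t in seq_len(nTubules)) {
    p <- .randomPointInCell(cell)
    y <- p[1L]; x <- p[2L]
    ang <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(len)) {
      y2 <- y + sin(ang); x2 <- x + cos(ang)
      tries <- 0L
      while ((y2 < 1 || y2 > H || x2 < 1 || x2 > W ||
              !cell[round(y2), round(x2)]) && tries < 25L) {
        ang <- stats::runif(1, 0, 2 * pi)
        y2 <- y + sin(ang); x2 <- x + cos(ang)
        tries <- tries + 1L
      }
      if (tries == 25L) break
      y <- y2; x <- x2
      marks[round(y), round(x)] <- 1
      ang <- ang + stats::rnorm(1, 0, 0.25)
    }
  }
  .dilateBinary(marks, 1L)
}

.drawFragments <- function(cell, nFragments) {
  H <- nrow(cell); W <- ncol(cell)
  pcy <- round(H / 2 - 0.1 * H)
  pcx <- round(W / 2 + 0.1 * W)
  sdev <- 0.1 * min(H, W)
  centers <- matrix(0L, nFragments, 2L)
  radii <- integer(nFragments)
  for (i in seq_len(nFragments)) {
    for (tries in 1:50) {
      cy <- round(pcy + stats::rnorm(1, 0, sdev))
      cx <- round(pcx + stats::rnorm(1, 0, sdev))
      if (cy >= 1 && cy <= H && cx >= 1 && cx <= W && cell[cy, cx]) break
      cy <- pcy; cx <- pcx
    }
    centers[i, ] <- c(cy, cx)
    radii[i] <- sample(2:3, 1L)
  }
  m <- matrix(0, H, W)
  for (i in seq_len(nFragments))
    m <- .stampDiscs(m, centers[i, , drop = FALSE], radii[i])
  m
}

.toroidalShiftCols <- function(m, shift) {
  if (shift == 0) return(m)
  W <- ncol(m)
  m[, ((seq_len(W) - 1L - shift) %% W) + 1L, drop = FALSE]
}

#' Generate a synthetic two-channel scene
#'
#' Renders a confocal-like field with known ground truth. The cell is a
#' filled ellipse covering about 60\% of the frame. Mitochondria are drawn
#' either as a tubular network (persistent random walks, dilated to ~3 px
#' width) or as fragmented perinuclear clusters of small discs. The
#' protein channel is drawn in the spatial relationship selected by
#' \code{proteinMode}: an annulus on the cell boundary (\code{membrane}),
#' random cytosolic puncta, a configurable fraction of pixels sampled
#' directly from the mitochondrial mask with the remainder as puncta
#' (\code{mito_colocalized}), a ring hugging the mitochondria
#' (\code{mito_ring}), or puncta confined to a band just outside them
#' (\code{mito_adjacent_puncta}). The protein pattern is then shifted
#' horizontally by \code{displacement} pixels with toroidal wrap-around, so
#' its area is conserved.
#'
#' Both binary patterns are recorded as ground-truth masks before
#' rendering: each channel is scaled to a peak intensity of 200, blurred
#' with a Gaussian PSF, offset by a linear background ramp, degraded by
#' Poisson-like shot noise and Gaussian read noise (both gained by
#' \code{noiseScale}; 0 disables noise entirely), and quantised to 16-bit
#' integers.
#'
#' @param config a [SceneConfig-class].
#' @return A [SyntheticScene-class]; identical configs give bit-identical
#'   scenes.
#' @examples
#' sc <- generateScene(SceneConfig(seed = 7, noiseScale = 0))
#' sum(maskPixels(truthMitoMask(sc)))
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  H <- config@height; W <- config@width

  .withSeed(config@seed, {
    cell <- .ellipseMask(H, W, H / 2, W / 2, 0.437 * H, 0.437 * W)

    mito <- switch(config@phenotype,
      network = .drawNetwork(cell, config@nTubules),
      fragmented_perinuclear = .drawFragments(cell, config@nFragments))

    nPuncta <- 40L
    prot <- matrix(0, H, W)
    if (config@proteinMode == "membrane") {
      inner <- .ellipseMask(H, W, H / 2, W / 2, 0.437 * H - 3, 0.437 * W - 3)
      prot[cell & !inner] <- 1
    } else if (config@proteinMode == "cytosolic_puncta") {
      centers <- t(vapply(seq_len(nPuncta),
                          function(i) .randomPointInCell(cell), integer(2)))
      prot <- .stampDiscs(prot, centers, 2L)
    } else if (config@proteinMode == "mito_colocalized") {
      mitoPix <- which(mito == 1)
      perm <- sample(mitoPix)
      centers <- t(vapply(seq_len(nPuncta),
                          function(i) .randomPointInCell(cell), integer(2)))
      nOn <- round(config@colocFraction * length(perm))
      if (nOn > 0) prot[perm[seq_len(nOn)]] <- 1
      nPun <- ceiling((1 - config@colocFraction) * nPuncta)
      if (nPun > 0)
        prot <- .stampDiscs(prot, centers[seq_len(nPun), , drop = FALSE], 2L)
    } else if (config@proteinMode == "mito_ring") {
      prot[.dilateBinary(mito, 3L) > 0 & mito == 0] <- 1
    } else if (config@proteinMode == "mito_adjacent_puncta") {
      band <- .dilateBinary(mito, 6L) > 0 & .dilateBinary(mito, 2L) == 0
      bandPix <- which(band)
      n <- min(30L, length(bandPix))
      chosen <- sample(bandPix, n)
      centers <- cbind((chosen - 1L) %% H + 1L, (chosen - 1L) %/% H + 1L)
      prot <- .stampDiscs(prot, centers, 2L)
    }

    prot <- .toroidalShiftCols(prot, round(config@displacement))

    amp <- 200
    bgRow <- matrix(seq_len(H) / H, H, W)
    bgCol <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
    bg <- config@backgroundGradientAmplitude * (bgRow + bgCol) / 2

    render <- function(mask) {
      img <- mask * amp
      if (config@psfSigma > 0)
        img <- EBImage::imageData(EBImage::gblur(img, config@psfSigma))
      img <- img + bg
      if (config@noiseScale > 0) {
        ns <- config@noiseScale
        shot <- stats::rpois(length(img), pmax(img, 0) / ns) * ns
        img <- shot + stats::rnorm(length(img), 0, ns)
        dim(img) <- c(H, W)
      }
      m <- pmin(pmax(round(img), 0), 65535)
      dim(m) <- c(H, W)
      m
    }

    image <- MultiChannelImage(list(mito = render(mito),
                                    protein = render(prot)),
                               bitDepth = "16")
    new("SyntheticScene", image = image,
        truthMitoMask = BinaryMask(mito, sourceChannel = "mito"),
        truthProteinMask = BinaryMask(prot, sourceChannel = "protein"),
        config = config)
  })
}

#' Generate a labelled batch of scenes
#'
#' Seeds are derived deterministically as \code{baseSeed + index}, so a
#' batch regenerates bit-identically from the same base seed.
#'
#' @param configs list of [SceneConfig-class] templates, one per scene
#'   (their own seeds are overridden).
#' @param groupLabels character vector of group labels, one per scene.
#' @param baseSeed integer base seed.
#' @param ids optional unique scene identifiers; default
#'   \code{<group>_<index-within-group>}.
#' @return A named list of [SyntheticScene-class]s with a \code{group}
#'   attribute on each element.
#' @export
sceneBatch <- function(configs, groupLabels, baseSeed = 1L, ids = NULL) {
  if (length(configs) == 0L)
    stop("configuration error: empty scene list", call. = FALSE)
  if (length(groupLabels) != length(configs))
    stop("configuration error: one group label per config is required",
         call. = FALSE)
  if (is.null(ids)) {
    idx <- stats::ave(seq_along(groupLabels), groupLabels, FUN = seq_along)
    ids <- paste(groupLabels, idx, sep = "_")
  }
  if (anyDuplicated(ids))
    stop("configuration error: duplicate scene identifiers", call. = FALSE)
  scenes <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg@seed <- as.integer(baseSeed + i)
    sc <- generateScene(cfg)
    attr(sc, "group") <- groupLabels[i]
    scenes[[i]] <- sc
  }
  names(scenes) <- ids
  scenes
}

.sceneConfigAsList <- function(cfg) {
  list(height = cfg@height, width = cfg@width, phenotype = cfg@phenotype,
       protein_mode = cfg@proteinMode, coloc_fraction = cfg@colocFraction,
       displacement = cfg@displacement, n_tubules = cfg@nTubules,
       n_fragments = cfg@nFragments, psf_sigma = cfg@psfSigma,
       background_gradient_amplitude = cfg@backgroundGradientAmplitude,
       noise_scale = cfg@noiseScale, seed = cfg@seed)
}

#' Write a scene to disk
#'
#' Writes the rendered channels as a two-page 16-bit TIFF plus a YAML
#' sidecar recording every generator parameter and the seed, so the scene
#' can be regenerated or re-analysed from the files alone.
#'
#' @param scene a [SyntheticScene-class].
#' @param prefix output path prefix; \code{<prefix>.tif} and
#'   \code{<prefix>.yaml} are written.
#' @return The TIFF path, invisibly.
#' @export
writeScene <- function(scene, prefix) {
  stopifnot(is(scene, "SyntheticScene"))
  tifPath <- paste0(prefix, ".tif")
  writeMultiChannelImage(scene@image, tifPath)
  yaml::write_yaml(.sceneConfigAsList(scene@config), paste0(prefix, ".yaml"))
  invisible(tifPath)
}
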