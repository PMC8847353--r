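## Pre-thresholding conditioning: frame median averaging, depth cropping,
## edge-aware local contrast enhancement, and slice-correspondence
## bookkeeping between PAT and light-sheet volumes.

#' Median-average a stack of repeated frames
#'
#' Per-pixel median over repeated acquisitions at one scan location (the
#' acquisition protocol records 10 frames per location). Even frame counts
#' use the mean of the two middle order statistics.
#'
#' @param frames list of 2D numeric matrices of identical shape.
#' @return A single 2D matrix.
#' @export
medianStack <- function(frames) {
  .assert(length(frames) >= 1L, "medianStack needs at least one frame")
  d <- dim(frames[[1]])
  for (f in frames)
    .assert(identical(dim(f), d), "all frames must share one shape")
  if (length(frames) == 1L) return(frames[[1]])
  arr <- array(unlist(frames, use.names = FALSE), c(d, length(frames)))
  apply(arr, c(1, 2), median)
}

#' Crop a volume to a fixed imaging depth
#'
#' Retains voxels whose depth coordinate (measured from the imaged surface;
#' the depth axis always increases away from that surface) is below
#' \code{depthMM}. PAT volumes are cropped to the light-sheet imaging depth
#' (2 mm for the cleared specimens) before post-processing.
#'
#' @param vol a \linkS4class{ChannelVolume}.
#' @param depthMM depth to retain, mm.
#' @return The cropped \linkS4class{ChannelVolume}; spacing unchanged.
#' @export
cropToDepth <- function(vol, depthMM) {
  stopifnot(is(vol, "ChannelVolume"))
  dz <- vol@spacing[2]
  extent <- dim(vol@voxels)[2] * dz
  .assert(depthMM <= extent + 1e-9,
          "crop depth %.3f mm exceeds volume depth extent %.3f mm",
          depthMM, extent)
  n_keep <- max(1L, floor(depthMM / dz + 1e-9))
  if (n_keep >= dim(vol@voxels)[2]) return(vol)
  channelVolume(vol@voxels[, seq_len(n_keep), , drop = FALSE], vol@spacing,
                vol@modality, vol@side, vol@wavelengthNM)
}

## Box mean filter with edge renormalization (window 2r+1).
.box2 <- function(mat, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  t(.conv_axis1(t(.conv_axis1(mat, k)), k))
}

#' Edge-aware local contrast enhancement
#'
#' Decomposes the image into an edge-preserving base layer and a detail
#' layer, amplifies the detail by \code{detailGain}, recombines, and clips
#' to the input range. \code{detailGain = 0} returns the input unchanged.
#' The base layer comes from a guided filter (the image guiding itself)
#' whose edge stop is set by \code{edgeThreshold} as a fraction of the
#' image intensity range; a plain Gaussian base is available for
#' comparison.
#'
#' @param img 2D numeric matrix with finite values.
#' @param detailGain non-negative detail amplification.
#' @param edgeThreshold edge-stop parameter as a fraction of the intensity
#'   range (guided-filter regularizer is its square).
#' @param radius filter window radius in pixels.
#' @param smoother \code{"guided"} (edge-preserving, default) or
#'   \code{"gaussian"}.
#' @return Enhanced 2D matrix, clipped to the input min/max.
#' @export
localContrastEnhance <- function(img, detailGain = 1, edgeThreshold = 0.1,
                                 radius = 8L, smoother = c("guided",
                                                           "gaussian")) {
  smoother <- match.arg(smoother)
  .assert(all(is.finite(img)), "image contains non-finite pixels")
  .assert(detailGain >= 0, "detailGain must be non-negative")
  if (detailGain == 0) return(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo) return(img)
  if (smoother == "guided") {
    eps <- (edgeThreshold * (hi - lo))^2
    mI <- .box2(img, radius)
    vI <- pmax(.box2(img * img, radius) - mI^2, 0)
    a <- vI / (vI + eps)
    b <- (1 - a) * mI
    base <- .box2(a, radius) * img + .box2(b, radius)
  } else {
    base <- .gauss_blur2(img, c(radius / 2, radius / 2))
  }
  out <- img + detailGain * (img - base)
  pmin(pmax(out, lo), hi)
}

#' Slice correspondence between two co-registered volumes
#'
#' Builds an explicit PAT-to-light-sheet slice mapping. In the physical
#' workflow slices are matched manually from overall morphology; this
#' helper refines a coarse (e.g. manual) map by maximizing normalized
#' cross-correlation within a search window, enforcing monotonicity along
#' the scan axis.
#'
#' @param volA,volB 3D arrays or \linkS4class{ChannelVolume}s resampled to
#'   a common in-plane grid.
#' @param coarseMap integer vector, length = slices of A: initial guess of
#'   the matching B slice per A slice (default identity).
#' @param window half-width of the search window around the coarse map.
#' @return A data.frame with columns \code{sliceA}, \code{sliceB},
#'   \code{ncc}, and attribute \code{method = "ncc_assist"}.
#' @export
matchSlicesNCC <- function(volA, volB, coarseMap = NULL, window = 2L) {
  a <- if (is(volA, "ChannelVolume")) volA@voxels else volA
  b <- if (is(volB, "ChannelVolume")) volB@voxels else volB
  .assert(identical(dim(a)[2:3], dim(b)[2:3]),
          "volumes must share the in-plane grid")
  nA <- dim(a)[1]; nB <- dim(b)[1]
  if (is.null(coarseMap)) coarseMap <- pmin(seq_len(nA), nB)
  .assert(length(coarseMap) == nA, "coarseMap must cover every A slice")
  .assert(!is.unsorted(coarseMap), "coarseMap must be monotonic")
  out_b <- integer(nA)
  out_ncc <- numeric(nA)
  prev <- 1L
  for (i in seq_len(nA)) {
    cand <- max(prev, coarseMap[i] - window):min(nB, coarseMap[i] + window)
    .assert(length(cand) >= 1L, "empty search window at slice %d", i)
    sa <- as.vector(a[i, , ])
    nccs <- vapply(cand, function(j) {
      sb <- as.vector(b[j, , ])
      if (sd(sa) == 0 || sd(sb) == 0) return(0)
      cor(sa, sb)
    }, numeric(1))
    k <- which.max(nccs)
    out_b[i] <- cand[k]
    out_ncc[i] <- nccs[k]
    prev <- cand[k]
  }
  res <- data.frame(sliceA = seq_len(nA), sliceB = out_b, ncc = out_ncc)
  attr(res, "method") <- "ncc_assist"
  res
}
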