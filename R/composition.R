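## Composition-positive pixel maps and percent composition.
##
## The canonical representation is the count form (sum of binarized
## slices); the averaged tissue-composition map is the derived view
## count/S, which keeps the sum and average formulations provably
## consistent.

#' Build the composition-positive pixel map of an analysis region
#'
#' Sums S aligned binarized slices per pixel, giving a count in 0..S of how
#' many slices express the channel's contrast there (S = 3 in the standard
#' region layout). The valid-pixel mask is the intersection of the
#' per-slice valid masks; invalid pixels carry no count.
#'
#' @param binaries list of S aligned 0/1 matrices, or a
#'   \linkS4class{BinaryVolume} together with \code{sliceIndices}.
#' @param valid optional list of per-slice logical masks (TRUE = valid);
#'   taken from the \linkS4class{BinaryVolume}'s exclusions when one is
#'   given.
#' @param sliceIndices scan-slice indices to use when \code{binaries} is a
#'   \linkS4class{BinaryVolume} (e.g. an \linkS4class{AnalysisRegion}'s
#'   slices).
#' @param channel channel tag recorded on the map.
#' @param regionID free-form region reference.
#' @return A \linkS4class{CompositionMap}.
#' @examples
#' s <- matrix(c(1, 0, 0, 1), 2)
#' m <- compositionPositiveMap(list(s, s, 1 - s))
#' countMap(m)
#' @export
compositionPositiveMap <- function(binaries, valid = NULL,
                                   sliceIndices = NULL,
                                   channel = "pat_lipid",
                                   regionID = "region") {
  if (is(binaries, "BinaryVolume")) {
    .assert(!is.null(sliceIndices),
            "sliceIndices required with a BinaryVolume")
    channel <- binaries@sourceModality
    valid <- lapply(sliceIndices, function(s) !binaries@excluded[s, , ])
    binaries <- lapply(sliceIndices, function(s) binaries@voxels[s, , ])
  }
  S <- length(binaries)
  .assert(S >= 1L, "at least one slice is required")
  d <- dim(binaries[[1]])
  for (b in binaries)
    .assert(identical(dim(b), d), "slice shapes differ")
  .assert(all(vapply(binaries, function(b) all(b %in% c(0, 1)), logical(1))),
          "slices must be binary")
  if (is.null(valid)) valid <- rep(list(matrix(TRUE, d[1], d[2])), S)
  .assert(length(valid) == S, "one valid mask per slice required")
  counts <- Reduce(`+`, binaries)
  vmask <- Reduce(`&`, valid)
  counts[!vmask] <- 0L
  new("CompositionMap", counts = matrix(as.integer(counts), d[1], d[2]),
      nSlices = as.integer(S), channel = channel,
      valid = matrix(as.logical(vmask), d[1], d[2]),
      regionID = as.character(regionID))
}

#' Tissue mask from one or more structural channels
#'
#' Defines "inside the biopsy" as the union of per-channel Otsu
#' foregrounds, cleaned per slice by morphological closing, hole filling
#' and retention of the largest connected component. Ultrasound or the
#' eosin channel are the intended structural inputs.
#'
#' @param vols a \linkS4class{ChannelVolume}, 3D array, or list of either,
#'   all on one voxel grid.
#' @param brushSize diameter of the closing brush in pixels (odd).
#' @return Logical 3D array, TRUE inside tissue.
#' @export
tissueMask <- function(vols, brushSize = 7L) {
  if (!is.list(vols)) vols <- list(vols)
  .assert(length(vols) >= 1L, "at least one channel required")
  arrs <- lapply(vols, function(v)
    if (is(v, "ChannelVolume")) v@voxels else v)
  d <- dim(arrs[[1]])
  fg <- array(FALSE, d)
  for (a in arrs) {
    .assert(identical(dim(a), d), "channels must share one voxel grid")
    fg <- fg | (a > otsuThreshold(a))
  }
  .assert(any(fg), "empty foreground: no tissue detected in any channel")
  brush <- EBImage::makeBrush(if (brushSize %% 2L == 1L) brushSize
                              else brushSize + 1L, "disc")
  out <- array(FALSE, d)
  for (s in seq_len(d[1])) {
    sl <- EBImage::closing(fg[s, , ] * 1, brush)
    sl <- EBImage::fillHull(sl)
    lab <- EBImage::bwlabel(sl)
    if (max(lab) >= 1) {
      sizes <- tabulate(lab[lab > 0])
      out[s, , ] <- lab == which.max(sizes)
    }
  }
  out
}

#' Percent composition of a binarized channel within a mask
#'
#' 100 x (positive, valid, in-mask pixels) / (valid, in-mask pixels). The
#' denominator is the valid tissue area, so artifact-excluded pixels drop
#' out of both numerator and denominator.
#'
#' @param binary a \linkS4class{BinaryVolume}, \linkS4class{CompositionMap}
#'   (a pixel is positive when its count is at least 1) or 0/1 array.
#' @param mask logical array of the same shape (e.g. from
#'   \code{\link{tissueMask}}); NULL uses all pixels.
#' @return Percent in [0, 100].
#' @export
percentComposition <- function(binary, mask = NULL) {
  if (is(binary, "CompositionMap")) {
    pos <- binary@counts >= 1L
    valid <- binary@valid
  } else if (is(binary, "BinaryVolume")) {
    pos <- binary@voxels == 1L
    valid <- !binary@excluded
  } else {
    pos <- binary == 1
    valid <- array(TRUE, dim(binary) %||% length(binary))
  }
  if (is.null(mask)) mask <- array(TRUE, dim(pos))
  .assert(identical(dim(mask), dim(pos)), "mask shape mismatch")
  denom <- sum(valid & mask)
  .assert(denom > 0, "zero valid pixels in mask")
  100 * sum(pos & valid & mask) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structural audit of an experiment layout
#'
#' Reports the region and image bookkeeping of a run: samples x regions
#' regions, regions x slices post-processed images. The standard layout of
#' 3 samples x 5 regions x 3 slices gives 15 regions and 45 images.
#'
#' @param nSamples number of samples (or an experiment config list with
#'   \code{samples}, \code{regions_per_sample}, \code{slices_per_region}).
#' @param nRegionsPerSample analysis regions per sample.
#' @param nSlicesPerRegion slices per region (3 in the standard layout).
#' @return List with \code{totalRegions} and \code{totalImages} plus the
#'   echoed layout.
#' @examples
#' regionPipelineCounts(3, 5, 3)  # 15 regions, 45 images
#' @export
regionPipelineCounts <- function(nSamples, nRegionsPerSample = 5L,
                                 nSlicesPerRegion = 3L) {
  if (is.list(nSamples)) {
    cfg <- nSamples
    nSlicesPerRegion <- cfg$slices_per_region %||% 3L
    nRegionsPerSample <- cfg$regions_per_sample %||% 5L
    nSamples <- if (!is.null(cfg$samples)) length(cfg$samples) else 1L
  }
  totalRegions <- nSamples * nRegionsPerSample
  list(samples = nSamples, regionsPerSample = nRegionsPerSample,
       slicesPerRegion = nSlicesPerRegion,
       totalRegions = totalRegions,
       totalImages = totalRegions * nSlicesPerRegion)
}
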