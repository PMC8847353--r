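## Channel binarization: Otsu's method for PAT channels, smoothed-histogram
## valley thresholds (averaged across analysis regions) for the light-sheet
## channels, with artifact-mask bookkeeping. Positivity is strict
## (intensity > threshold) throughout.

#' Otsu threshold of an image
#'
#' Histogram threshold maximizing the between-class variance
#' \eqn{\sigma_b^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the two
#' classes induced by \code{intensity > t}. Intensities are binned over
#' their min-max range (256 bins by default); ties break toward the lower
#' threshold.
#'
#' @param img numeric array (any shape) with at least two distinct values.
#' @param nBins number of histogram bins.
#' @return The threshold value (upper edge of the selected bin), on the
#'   original intensity scale.
#' @examples
#' img <- c(rep(10, 50), rep(200, 50))
#' otsuThreshold(img)  # separates the two modes
#' @export
otsuThreshold <- function(img, nBins = 256L) {
  v <- as.vector(img)
  .assert(all(is.finite(v)), "image contains non-finite values")
  lo <- min(v); hi <- max(v)
  .assert(hi > lo, "constant image: no Otsu threshold exists")
  nBins <- as.integer(nBins)
  bin <- pmin(nBins, floor((v - lo) / (hi - lo) * nBins) + 1L)
  counts <- tabulate(bin, nBins)
  p <- counts / length(v)
  w0 <- cumsum(p)
  ## exact per-bin intensity sums (not bin centres), so the maximization
  ## agrees with an exhaustive pixel-level search
  sums <- numeric(nBins)
  rs <- rowsum(v, bin)
  sums[as.integer(rownames(rs))] <- rs
  mu_cum <- cumsum(sums) / length(v)
  mu_tot <- mu_cum[nBins]
  s <- seq_len(nBins - 1L)
  w1 <- 1 - w0[s]
  valid <- w0[s] > 0 & w1 > 0
  sigma_b <- rep(-Inf, nBins - 1L)
  sigma_b[valid] <- (mu_tot * w0[s][valid] - mu_cum[s][valid])^2 /
    (w0[s][valid] * w1[valid])
  k <- which.max(sigma_b)  # first max = lowest threshold on ties
  lo + k * (hi - lo) / nBins
}

#' Smoothed-histogram valley threshold for one analysis region
#'
#' Kernel-smooths the intensity histogram and returns the deepest valley
#' between the two most prominent modes. Unimodal regions fall back to a
#' configured intensity percentile, with a warning.
#'
#' @param img numeric array for one region (2D slice or small stack).
#' @param bandwidth kernel bandwidth on the intensity axis; the default,
#'   5\% of the intensity range, smooths over sub-structure (noise, stripe
#'   artifacts) within a tissue mode so the valley separates the two
#'   macroscopic modes.
#' @param fallbackPercentile percentile in (0,1) used when the smoothed
#'   histogram is unimodal (default 0.95).
#' @return The threshold value.
#' @export
histogramRegionThreshold <- function(img, bandwidth = NULL,
                                     fallbackPercentile = 0.95) {
  v <- as.vector(img)
  .assert(all(is.finite(v)), "region contains non-finite values")
  .assert(length(unique(v)) >= 2L, "constant region: no threshold exists")
  if (is.null(bandwidth)) bandwidth <- 0.05 * diff(range(v))
  dens <- density(v, bw = bandwidth, n = 512)
  y <- dens$y; x <- dens$x
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  peaks <- which(is_peak)
  if (length(peaks) < 2L) {
    warning("unimodal histogram: falling back to the ",
            round(100 * fallbackPercentile), "th percentile threshold")
    return(as.numeric(quantile(v, fallbackPercentile)))
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  x[valley]
}

#' Average region thresholds and binarize a volume
#'
#' Averages per-region threshold points arithmetically, applies the
#' averaged threshold to the whole dataset (positive = intensity strictly
#' above it), and zeroes artifact-masked voxels while recording them as
#' excluded so downstream denominators omit them.
#'
#' @param thresholds numeric vector of per-region threshold points.
#' @param vol a \linkS4class{ChannelVolume} or numeric array.
#' @param artifactMask optional logical array (TRUE = excluded), same shape.
#' @param invert if TRUE, positivity is intensity strictly below the
#'   threshold (used to read lipid as the eosin-dim complement of stroma).
#' @return A \linkS4class{BinaryVolume}.
#' @export
averageAndApply <- function(thresholds, vol, artifactMask = NULL,
                            invert = FALSE) {
  .assert(length(thresholds) >= 1L, "empty threshold list")
  arr <- if (is(vol, "ChannelVolume")) vol@voxels else vol
  if (length(dim(arr)) == 2L) arr <- array(arr, c(1L, dim(arr)))
  t_avg <- mean(thresholds)
  bin <- if (invert) (arr < t_avg) else (arr > t_avg)
  bin <- array(as.integer(bin), dim(arr))
  excl <- if (is.null(artifactMask)) array(FALSE, dim(arr))
          else array(as.logical(artifactMask), dim(arr))
  .assert(identical(dim(excl), dim(arr)),
          "artifact mask shape does not match the volume")
  bin[excl] <- 0L
  new("BinaryVolume", voxels = bin,
      sourceModality = if (is(vol, "ChannelVolume")) vol@modality
                       else "pat_lipid",
      thresholds = as.numeric(thresholds), appliedThreshold = t_avg,
      excluded = excl)
}

#' Otsu-binarize a PAT volume per slice or per volume
#'
#' Applies \code{\link{otsuThreshold}} independently to each scan slice
#' (default, feeding the per-region analysis) or once to the whole volume.
#'
#' @param vol a \linkS4class{ChannelVolume} or 3D array.
#' @param perSlice threshold each scan slice separately (default TRUE).
#' @param nBins histogram bins for Otsu.
#' @param artifactMask optional logical exclusion array.
#' @return A \linkS4class{BinaryVolume}; \code{thresholds} holds the
#'   per-slice (or single) threshold values.
#' @export
otsuBinarize <- function(vol, perSlice = TRUE, nBins = 256L,
                         artifactMask = NULL) {
  arr <- if (is(vol, "ChannelVolume")) vol@voxels else vol
  if (length(dim(arr)) == 2L) arr <- array(arr, c(1L, dim(arr)))
  bin <- array(0L, dim(arr))
  if (perSlice) {
    th <- vapply(seq_len(dim(arr)[1]), function(s)
      otsuThreshold(arr[s, , ], nBins), numeric(1))
    for (s in seq_len(dim(arr)[1]))
      bin[s, , ] <- as.integer(arr[s, , ] > th[s])
  } else {
    th <- otsuThreshold(arr, nBins)
    bin <- array(as.integer(arr > th), dim(arr))
  }
  excl <- if (is.null(artifactMask)) array(FALSE, dim(arr))
          else array(as.logical(artifactMask), dim(arr))
  bin[excl] <- 0L
  new("BinaryVolume", voxels = bin,
      sourceModality = if (is(vol, "ChannelVolume")) vol@modality
                       else "pat_lipid",
      thresholds = as.numeric(th), appliedThreshold = mean(th),
      excluded = excl)
}
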