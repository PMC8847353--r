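## Accessor and show() methods.

#' @rdname accessors
setMethod("voxelData", "ChannelVolume", function(object) object@voxels)

#' @rdname accessors
setMethod("voxelData", "BinaryVolume", function(object) object@voxels)

#' @rdname accessors
setMethod("spacingMM", "ChannelVolume", function(object) object@spacing)

#' @rdname accessors
setMethod("modality", "ChannelVolume", function(object) object@modality)

#' @rdname accessors
setMethod("modality", "BinaryVolume", function(object) object@sourceModality)

#' @rdname accessors
setMethod("imagingSide", "ChannelVolume", function(object) object@side)

#' @rdname accessors
setMethod("excludedMask", "BinaryVolume", function(object) object@excluded)

#' @rdname accessors
setMethod("countMap", "CompositionMap", function(object) object@counts)

#' @rdname accessors
setMethod("fractionMap", "CompositionMap",
          function(object) object@counts / object@nSlices)

#' @rdname accessors
setMethod("validMask", "CompositionMap", function(object) object@valid)

#' @rdname accessors
setMethod("slicesPerRegion", "CompositionMap", function(object) object@nSlices)

setMethod("show", "ChannelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ChannelVolume [%s, %s]\n", object@modality, object@side))
  cat(sprintf("  %d slices x %d depth x %d lateral voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): scan %.3f, depth %.3f, lateral %.3f\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  extent (mm): %.2f x %.2f x %.2f\n",
              d[1] * object@spacing[1], d[2] * object@spacing[2],
              d[3] * object@spacing[3]))
  if (length(object@wavelengthNM))
    cat(sprintf("  wavelength: %g nm\n", object@wavelengthNM))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryVolume [%s]\n", object@sourceModality))
  cat(sprintf("  %d x %d x %d voxels; positive fraction %.3f\n",
              d[1], d[2], d[3], mean(object@voxels)))
  cat(sprintf("  applied threshold %.4g (from %d region threshold%s)\n",
              object@appliedThreshold, length(object@thresholds),
              if (length(object@thresholds) == 1L) "" else "s"))
  cat(sprintf("  excluded voxels: %.2f%%\n", 100 * mean(object@excluded)))
})

setMethod("show", "CompositionMap", function(object) {
  cat(sprintf("CompositionMap [%s] region %s\n", object@channel,
              object@regionID))
  cat(sprintf("  %d x %d pixels, counts 0..%d; valid %.1f%%\n",
              nrow(object@counts), ncol(object@counts), object@nSlices,
              100 * mean(object@valid)))
  tb <- table(factor(object@counts[object@valid],
                     levels = 0:object@nSlices))
  cat("  count histogram:", paste(sprintf("%s:%d", names(tb), tb),
                                  collapse = " "), "\n")
})

setMethod("show", "AnalysisRegion", function(object) {
  cat(sprintf("AnalysisRegion %d [%s, %s]: slices %s (histology slice %d)\n",
              object@regionIndex, object@sampleID, object@side,
              paste(object@sliceIndices, collapse = ","),
              object@histologySlice))
})

setMethod("show", "ROIBox", function(object) {
  cat(sprintf("ROIBox [%s] %.2f mm square at (%.2f, %.2f) mm, region %d\n",
              object@label, object@sideMM, object@originMM[1],
              object@originMM[2], object@regionIndex))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labels)
  cat(sprintf("PhantomTruth: %d x %d x %d voxels at %.3f mm\n",
              d[1], d[2], d[3], object@spacingMM[1]))
  tis <- sum(object@tissue)
  cat(sprintf("  tissue voxels: %d (%.1f%%); nuclei: %d\n", tis,
              100 * tis / length(object@tissue), nrow(object@nuclei)))
  for (cls in names(.PHANTOM_CLASSES)[-1]) {
    n <- sum(object@labels == .PHANTOM_CLASSES[cls])
    if (n > 0)
      cat(sprintf("  %-11s %6.2f%% of tissue\n", cls, 100 * n / tis))
  }
})

#' Realized tissue-class volume fractions of a phantom
#'
#' Fraction of in-tissue voxels carrying each tissue-class label.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @return Named numeric vector over the tissue classes.
#' @export
classFractions <- function(truth) {
  stopifnot(is(truth, "PhantomTruth"))
  tis <- sum(truth@tissue)
  vapply(.PHANTOM_CLASSES[-1], function(code) {
    sum(truth@labels == code) / tis
  }, numeric(1))
}
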