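## S4 classes for the multimodal biopsy data model.

## Closed modality vocabulary.
.MODALITIES <- c("pat_lipid", "pat_hemoglobin", "pat_off", "ultrasound",
                 "ispim_eosin", "ispim_nuclei", "ispim_lipid")
.SIDES <- c("anterior", "posterior")

## Phantom tissue class codes (label volume values).
.PHANTOM_CLASSES <- c(background = 0L, adipose = 1L, stroma = 2L,
                      duct_lumen = 3L, duct_wall = 4L, carcinoma = 5L,
                      vessel = 6L)

#' ChannelVolume: one modality's 3D scalar image
#'
#' Stores a single imaging channel as a 3D array in (scan, depth, lateral)
#' axis order with physical voxel spacing in millimetres. The depth axis
#' always increases away from the imaged surface, so anterior and posterior
#' acquisitions share one convention.
#'
#' @slot voxels 3D numeric array, axis order (scan, depth, lateral).
#' @slot spacing named numeric of length 3 (scan, depth, lateral), mm/voxel.
#' @slot modality one of \code{pat_lipid}, \code{pat_hemoglobin},
#'   \code{pat_off}, \code{ultrasound}, \code{ispim_eosin},
#'   \code{ispim_nuclei}, \code{ispim_lipid}.
#' @slot side \code{anterior} or \code{posterior}.
#' @slot wavelengthNM optional acquisition wavelength in nm (length 0 or 1).
#' @exportClass ChannelVolume
setClass("ChannelVolume",
  representation(voxels = "array", spacing = "numeric",
                 modality = "character", side = "character",
                 wavelengthNM = "numeric"),
  prototype(wavelengthNM = numeric(0)))

setValidity("ChannelVolume", function(object) {
  msgs <- character(0)
  if (length(dim(object@voxels)) != 3L || length(object@voxels) == 0L)
    msgs <- c(msgs, "voxels must be a non-empty 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive finite values")
  if (!all(is.finite(object@voxels)))
    msgs <- c(msgs, "voxel intensities must be finite")
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msgs <- c(msgs, sprintf("modality must be one of: %s",
                            paste(.MODALITIES, collapse = ", ")))
  if (length(object@side) != 1L || !object@side %in% .SIDES)
    msgs <- c(msgs, "side must be 'anterior' or 'posterior'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChannelVolume
#'
#' @param voxels 3D numeric array in (scan, depth, lateral) order.
#' @param spacing numeric length-3 voxel spacing in mm (scan, depth, lateral).
#' @param modality modality tag.
#' @param side acquisition side, \code{"anterior"} (default) or
#'   \code{"posterior"}.
#' @param wavelengthNM optional wavelength in nm.
#' @return A \linkS4class{ChannelVolume}.
#' @examples
#' v <- channelVolume(array(runif(60), c(3, 4, 5)), c(0.193, 0.03, 0.05),
#'                    "pat_lipid", wavelengthNM = 1210)
#' dim(voxelData(v))
#' @export
channelVolume <- function(voxels, spacing, modality, side = "anterior",
                          wavelengthNM = numeric(0)) {
  spacing <- as.numeric(spacing)
  names(spacing) <- .AXES
  new("ChannelVolume", voxels = voxels, spacing = spacing,
      modality = modality, side = side,
      wavelengthNM = as.numeric(wavelengthNM))
}

#' AnalysisRegion: a 3-slice window matched to one histology plane
#'
#' A region is exactly three contiguous slices along the scan axis; the
#' middle slice is the histology-matched plane. With a 0.193 mm scan step a
#' region spans 0.386 mm of biopsy length.
#'
#' @slot sampleID sample identifier.
#' @slot side acquisition side.
#' @slot regionIndex region number within the side (1-based).
#' @slot sliceIndices exactly three contiguous 1-based scan-slice indices.
#' @slot histologySlice index of the histology-matched (middle) slice.
#' @exportClass AnalysisRegion
setClass("AnalysisRegion",
  representation(sampleID = "character", side = "character",
                 regionIndex = "integer", sliceIndices = "integer",
                 histologySlice = "integer"))

setValidity("AnalysisRegion", function(object) {
  s <- object@sliceIndices
  msgs <- character(0)
  if (length(s) != 3L) msgs <- c(msgs, "a region has exactly 3 slices")
  else {
    if (!all(diff(s) == 1L)) msgs <- c(msgs, "slice indices must be contiguous")
    if (length(object@histologySlice) != 1L || object@histologySlice != s[2])
      msgs <- c(msgs, "histology-matched slice must be the middle slice")
    if (any(s < 1L)) msgs <- c(msgs, "slice indices must be >= 1")
  }
  if (!object@side %in% .SIDES) msgs <- c(msgs, "invalid side")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnalysisRegion
#'
#' @param sampleID sample identifier.
#' @param side acquisition side.
#' @param regionIndex region number (1..5 in the standard layout).
#' @param sliceIndices three contiguous scan-slice indices; the middle one is
#'   taken as the histology-matched plane.
#' @return An \linkS4class{AnalysisRegion}.
#' @export
analysisRegion <- function(sampleID, side, regionIndex, sliceIndices) {
  sliceIndices <- as.integer(sliceIndices)
  new("AnalysisRegion", sampleID = as.character(sampleID), side = side,
      regionIndex = as.integer(regionIndex), sliceIndices = sliceIndices,
      histologySlice = sliceIndices[2])
}

#' BinaryVolume: a binarized channel with exclusion bookkeeping
#'
#' @slot voxels integer 0/1 array, same geometry as the source channel.
#' @slot sourceModality modality of the thresholded channel.
#' @slot thresholds per-region threshold points used.
#' @slot appliedThreshold the single (averaged) threshold actually applied.
#' @slot excluded logical array flagging artifact-masked voxels; excluded
#'   voxels are 0 in \code{voxels} and omitted from denominators downstream.
#' @exportClass BinaryVolume
setClass("BinaryVolume",
  representation(voxels = "array", sourceModality = "character",
                 thresholds = "numeric", appliedThreshold = "numeric",
                 excluded = "array"))

setValidity("BinaryVolume", function(object) {
  msgs <- character(0)
  if (!all(object@voxels %in% c(0L, 1L)))
    msgs <- c(msgs, "binary voxels must be 0 or 1")
  if (!identical(dim(object@voxels), dim(object@excluded)))
    msgs <- c(msgs, "excluded mask must match voxel geometry")
  if (any(object@voxels[object@excluded] != 0L))
    msgs <- c(msgs, "excluded voxels must be 0")
  if (length(msgs)) msgs else TRUE
})

#' CompositionMap: per-pixel composition-positive counts for one region
#'
#' Counts how many of the S binarized slices in an analysis region are
#' positive at each pixel (0..S; S = 3 in the standard layout). The fraction
#' map count/S is a derived view, keeping the "sum of binarized images" and
#' "average of binarized images" formulations provably consistent.
#'
#' @slot counts integer matrix (depth x lateral) of positive-slice counts.
#' @slot nSlices S, the number of slices summed.
#' @slot channel source modality tag.
#' @slot valid logical matrix; FALSE marks artifact/out-of-tissue pixels that
#'   carry no count and are excluded from denominators.
#' @slot regionID free-form region reference.
#' @exportClass CompositionMap
setClass("CompositionMap",
  representation(counts = "matrix", nSlices = "integer",
                 channel = "character", valid = "matrix",
                 regionID = "character"))

setValidity("CompositionMap", function(object) {
  msgs <- character(0)
  if (any(object@counts < 0L) || any(object@counts > object@nSlices))
    msgs <- c(msgs, "counts must lie in 0..nSlices")
  if (!identical(dim(object@counts), dim(object@valid)))
    msgs <- c(msgs, "valid mask must match count geometry")
  if (any(object@counts[!object@valid] != 0L))
    msgs <- c(msgs, "invalid pixels must carry no count")
  if (length(msgs)) msgs else TRUE
})

#' ROIBox: a square scoring region in physical units
#'
#' @slot sampleID sample identifier.
#' @slot side acquisition side.
#' @slot regionIndex analysis-region number the ROI belongs to.
#' @slot originMM in-plane origin (depth_mm, lateral_mm) of the box corner.
#' @slot sideMM box side length in mm (default rubric size 0.66).
#' @slot label \code{"cancerous"} or \code{"non_cancerous"}.
#' @exportClass ROIBox
setClass("ROIBox",
  representation(sampleID = "character", side = "character",
                 regionIndex = "integer", originMM = "numeric",
                 sideMM = "numeric", label = "character"))

setValidity("ROIBox", function(object) {
  msgs <- character(0)
  if (length(object@originMM) != 2L || any(object@originMM < 0))
    msgs <- c(msgs, "originMM must be 2 non-negative coordinates")
  if (length(object@sideMM) != 1L || object@sideMM <= 0)
    msgs <- c(msgs, "sideMM must be > 0")
  if (!object@label %in% c("cancerous", "non_cancerous"))
    msgs <- c(msgs, "label must be 'cancerous' or 'non_cancerous'")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ROIBox
#'
#' @param originMM in-plane (depth, lateral) origin of the box in mm.
#' @param sideMM side length in mm; the default 0.66 is one third of the
#'   2 mm imaging depth.
#' @param label class label, \code{"cancerous"} or \code{"non_cancerous"}.
#' @param sampleID,side,regionIndex bookkeeping references.
#' @return An \linkS4class{ROIBox}.
#' @export
roiBox <- function(originMM, sideMM = 0.66, label = "non_cancerous",
                   sampleID = "sample", side = "anterior", regionIndex = 1L) {
  new("ROIBox", sampleID = as.character(sampleID), side = side,
      regionIndex = as.integer(regionIndex), originMM = as.numeric(originMM),
      sideMM = as.numeric(sideMM), label = label)
}

#' PhantomParams: generator settings for the synthetic biopsy phantom
#'
#' Defaults emulate the study conditions: a roughly 5.3 x 4.7 x 2 mm fixed
#' breast-biopsy block scanned step-wise at 0.193 mm, imaged from both
#' sides, containing adipose lobules, fibrous stroma, ducts with
#' nuclei-dense walls, carcinoma foci (stroma-rich, lipid-poor,
#' nuclei-dense) and hemoglobin-rich vessels, with single-exponential
#' fluence decay in depth and per-channel noise.
#'
#' @slot extentMM physical extent (scan, depth, lateral), mm.
#' @slot patSpacingMM PAT voxel spacing (scan step 0.193 mm, depth, lateral).
#' @slot ispimSpacingMM light-sheet voxel spacing, mm (finer, near-isotropic).
#' @slot truthSpacingMM lattice spacing of the ground-truth volume, mm.
#' @slot fractions named target volume fractions (adipose, duct, carcinoma,
#'   vessel) of the tissue volume; the remainder is stroma.
#' @slot adiposeRadiusMM lobule radius range, mm.
#' @slot carcinomaFoci number of carcinoma foci.
#' @slot carcinomaRadiusMM focus radius range, mm.
#' @slot ductCount,ductRadiusMM,ductWallMM duct geometry.
#' @slot vesselCount,vesselRadiusMM vessel geometry.
#' @slot nucleiDensity nuclei per mm^3 by class (stylized, not literal
#'   cellularity): carcinoma ~ duct wall >> stroma > adipose.
#' @slot stromalLipidFraction,stromalLipidLevel sparse scattered lipid in
#'   stroma (fraction of stroma voxels; concentration value).
#' @slot fluenceDecayMM effective optical attenuation length, mm.
#' @slot patBlurSigmaMM anisotropic PAT point-spread sigma per axis, mm.
#' @slot noiseSD additive Gaussian noise sd per channel (named);
#'   \code{ultrasound} entry is the multiplicative speckle variance.
#' @slot stripeAmplitude,stripePeriodMM stitching-stripe artifact for the
#'   light-sheet channels (multiplicative sine, amplitude 0 disables).
#' @slot marginMM background margin around the tissue block, mm.
#' @slot depthCropMM imaging depth retained after cropping, mm.
#' @slot seed master random seed; fixed seed gives bit-identical output.
#' @exportClass PhantomParams
setClass("PhantomParams",
  representation(extentMM = "numeric", patSpacingMM = "numeric",
                 ispimSpacingMM = "numeric", truthSpacingMM = "numeric",
                 fractions = "numeric", adiposeRadiusMM = "numeric",
                 carcinomaFoci = "integer", carcinomaRadiusMM = "numeric",
                 ductCount = "integer", ductRadiusMM = "numeric",
                 ductWallMM = "numeric", vesselCount = "integer",
                 vesselRadiusMM = "numeric", nucleiDensity = "numeric",
                 stromalLipidFraction = "numeric",
                 stromalLipidLevel = "numeric", fluenceDecayMM = "numeric",
                 patBlurSigmaMM = "numeric", noiseSD = "numeric",
                 stripeAmplitude = "numeric", stripePeriodMM = "numeric",
                 marginMM = "numeric", depthCropMM = "numeric",
                 seed = "integer"))

setValidity("PhantomParams", function(object) {
  msgs <- character(0)
  if (any(object@extentMM <= 0) || any(object@patSpacingMM <= 0) ||
      any(object@ispimSpacingMM <= 0) || any(object@truthSpacingMM <= 0))
    msgs <- c(msgs, "extents and spacings must be strictly positive")
  fr <- object@fractions
  if (any(fr < 0) || any(fr > 1))
    msgs <- c(msgs, "class volume fractions must lie in [0,1]")
  if (sum(fr) > 1)
    msgs <- c(msgs, sprintf(
      "class volume fractions sum to %.3f > 1 (remainder must be stroma)",
      sum(fr)))
  if (object@fluenceDecayMM <= 0)
    msgs <- c(msgs, "fluence decay length must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct PhantomParams
#'
#' All arguments have study-scale defaults; override any subset.
#'
#' @param extentMM extent (scan, depth, lateral) in mm.
#' @param patSpacingMM PAT voxel spacing in mm.
#' @param ispimSpacingMM light-sheet voxel spacing in mm.
#' @param truthSpacingMM ground-truth lattice spacing in mm.
#' @param fractions named tissue-class volume fractions (adipose, duct,
#'   carcinoma, vessel); remainder is stroma.
#' @param adiposeRadiusMM,carcinomaFoci,carcinomaRadiusMM,ductCount,
#'   ductRadiusMM,ductWallMM,vesselCount,vesselRadiusMM geometry settings.
#' @param nucleiDensity nuclei per mm^3 by class.
#' @param stromalLipidFraction,stromalLipidLevel scattered stromal lipid.
#' @param fluenceDecayMM effective attenuation length, mm.
#' @param patBlurSigmaMM PAT point-spread sigma (scan, depth, lateral), mm.
#' @param noiseSD named per-channel noise levels.
#' @param stripeAmplitude,stripePeriodMM stitching-stripe artifact.
#' @param marginMM background margin, mm.
#' @param depthCropMM retained imaging depth, mm.
#' @param seed master seed.
#' @return A \linkS4class{PhantomParams}.
#' @examples
#' p <- phantomParams(extentMM = c(2, 1, 2), seed = 1)
#' @export
phantomParams <- function(extentMM = c(5.34, 1.98, 4.71),
                          patSpacingMM = c(0.193, 0.03, 0.05),
                          ispimSpacingMM = c(0.01, 0.01, 0.01),
                          truthSpacingMM = c(0.02, 0.02, 0.02),
                          fractions = c(adipose = 0.30, duct = 0.04,
                                        carcinoma = 0.10, vessel = 0.02),
                          adiposeRadiusMM = c(0.20, 0.45),
                          carcinomaFoci = 5L,
                          carcinomaRadiusMM = c(0.25, 0.60),
                          ductCount = 3L, ductRadiusMM = 0.15,
                          ductWallMM = 0.06,
                          vesselCount = 4L, vesselRadiusMM = 0.06,
                          nucleiDensity = c(adipose = 50, stroma = 400,
                                            duct_wall = 4000,
                                            carcinoma = 4000, vessel = 200),
                          stromalLipidFraction = 0.05,
                          stromalLipidLevel = 0.2,
                          fluenceDecayMM = 1.5,
                          patBlurSigmaMM = c(0.10, 0.04, 0.08),
                          noiseSD = c(pat_lipid = 0.02,
                                      pat_hemoglobin = 0.02,
                                      pat_off = 0.02, ultrasound = 0.3,
                                      ispim_eosin = 0.02,
                                      ispim_nuclei = 0.02),
                          stripeAmplitude = 0.10, stripePeriodMM = 0.5,
                          marginMM = 0.2, depthCropMM = 2.0, seed = 1L) {
  defaults <- c(adipose = 0, duct = 0, carcinoma = 0, vessel = 0)
  defaults[names(fractions)] <- fractions
  new("PhantomParams", extentMM = as.numeric(extentMM),
      patSpacingMM = as.numeric(patSpacingMM),
      ispimSpacingMM = as.numeric(ispimSpacingMM),
      truthSpacingMM = as.numeric(truthSpacingMM),
      fractions = defaults,
      adiposeRadiusMM = as.numeric(adiposeRadiusMM),
      carcinomaFoci = as.integer(carcinomaFoci),
      carcinomaRadiusMM = as.numeric(carcinomaRadiusMM),
      ductCount = as.integer(ductCount),
      ductRadiusMM = as.numeric(ductRadiusMM),
      ductWallMM = as.numeric(ductWallMM),
      vesselCount = as.integer(vesselCount),
      vesselRadiusMM = as.numeric(vesselRadiusMM),
      nucleiDensity = nucleiDensity,
      stromalLipidFraction = as.numeric(stromalLipidFraction),
      stromalLipidLevel = as.numeric(stromalLipidLevel),
      fluenceDecayMM = as.numeric(fluenceDecayMM),
      patBlurSigmaMM = as.numeric(patBlurSigmaMM),
      noiseSD = noiseSD,
      stripeAmplitude = as.numeric(stripeAmplitude),
      stripePeriodMM = as.numeric(stripePeriodMM),
      marginMM = as.numeric(marginMM),
      depthCropMM = as.numeric(depthCropMM), seed = as.integer(seed))
}

#' PhantomTruth: ground truth for the synthetic biopsy
#'
#' @slot labels integer class volume on the truth lattice (0 background,
#'   1 adipose, 2 stroma, 3 duct lumen, 4 duct wall, 5 carcinoma, 6 vessel).
#' @slot lipid,hemoglobin chromophore concentration maps in [0,1], same
#'   lattice as \code{labels}; hemoglobin is non-zero only in vessels,
#'   lipid only in adipose and scattered stromal lipid.
#' @slot nuclei n x 3 matrix of nucleus centres (scan, depth, lateral), mm.
#' @slot tissue logical mask of in-tissue voxels.
#' @slot spacingMM truth lattice spacing, mm.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(labels = "array", lipid = "array", hemoglobin = "array",
                 nuclei = "matrix", tissue = "array", spacingMM = "numeric"))

setValidity("PhantomTruth", function(object) {
  msgs <- character(0)
  d <- dim(object@labels)
  if (!identical(d, dim(object@lipid)) || !identical(d, dim(object@hemoglobin)) ||
      !identical(d, dim(object@tissue)))
    msgs <- c(msgs, "label, concentration and tissue volumes must share geometry")
  lab <- object@labels
  if (any(object@hemoglobin > 0 & lab != .PHANTOM_CLASSES["vessel"]))
    msgs <- c(msgs, "hemoglobin must be zero outside vessels")
  if (any(object@lipid > 0 &
          !(lab %in% .PHANTOM_CLASSES[c("adipose", "stroma")])))
    msgs <- c(msgs, "lipid must be zero outside adipose/stromal tissue")
  if (nrow(object@nuclei) > 0) {
    idx <- cbind(
      .nn_coord(object@nuclei[, 1], object@spacingMM[1], d[1]),
      .nn_coord(object@nuclei[, 2], object@spacingMM[2], d[2]),
      .nn_coord(object@nuclei[, 3], object@spacingMM[3], d[3]))
    if (!all(object@tissue[idx]))
      msgs <- c(msgs, "every nucleus must lie inside the tissue mask")
  }
  if (length(msgs)) msgs else TRUE
})

## mm coordinate -> clipped 1-based voxel index
.nn_coord <- function(x_mm, dx, n) pmin(n, pmax(1L, floor(x_mm / dx) + 1L))
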