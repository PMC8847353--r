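## Generics for the data model accessors.

#' Accessors for patquant data objects
#'
#' \code{voxelData} returns the raw voxel array of a volume,
#' \code{spacingMM} its physical voxel spacing, \code{modality} and
#' \code{imagingSide} its tags; \code{countMap}, \code{fractionMap},
#' \code{validMask} and \code{slicesPerRegion} expose a
#' \linkS4class{CompositionMap}; \code{excludedMask} exposes a
#' \linkS4class{BinaryVolume}'s artifact exclusions.
#'
#' @param object a patquant S4 object.
#' @return The requested component.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("spacingMM", function(object) standardGeneric("spacingMM"))

#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("imagingSide", function(object) standardGeneric("imagingSide"))

#' @rdname accessors
#' @export
setGeneric("countMap", function(object) standardGeneric("countMap"))

#' @rdname accessors
#' @export
setGeneric("fractionMap", function(object) standardGeneric("fractionMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("slicesPerRegion", function(object) standardGeneric("slicesPerRegion"))

#' @rdname accessors
#' @export
setGeneric("excludedMask", function(object) standardGeneric("excludedMask"))
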