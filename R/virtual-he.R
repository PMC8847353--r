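## Virtual H&E pseudo-coloring of the two light-sheet channels, for visual
## QC only. A Beer-Lambert absorbance model with standard hematoxylin and
## eosin stain color vectors; excluded from all quantitative paths.

## Per-RGB-channel optical densities of the two stains (unit concentration).
.HE_COLORS <- list(hematoxylin = c(R = 0.65, G = 0.70, B = 0.29),
                   eosin = c(R = 0.07, G = 0.99, B = 0.11))

#' Pseudo-color a light-sheet slice pair as virtual H&E
#'
#' Maps the nuclei (DRAQ5) channel through a hematoxylin-like absorbance
#' and the eosin channel through an eosin-like absorbance:
#' RGB = exp(-(k_H * nuclei + k_E * eosin)) per stain color vector. Zero
#' input renders white; output darkens monotonically in each input.
#'
#' @param eosin,nuclei co-registered non-negative 2D matrices of one shape.
#' @param gains length-2 numeric (hematoxylin, eosin) concentration gains.
#' @return 3D array (rows x cols x RGB) in [0,1], with a
#'   \code{provenance} attribute recording the gains.
#' @examples
#' rgb <- pseudoColorHE(matrix(0, 2, 2), matrix(0, 2, 2))
#' rgb[1, 1, ]  # pure white
#' @export
pseudoColorHE <- function(eosin, nuclei, gains = c(hematoxylin = 1.2,
                                                   eosin = 1.0)) {
  .assert(identical(dim(eosin), dim(nuclei)),
          "eosin and nuclei slices must share one shape")
  .assert(all(eosin >= 0) && all(nuclei >= 0),
          "channel intensities must be non-negative")
  d <- dim(eosin)
  out <- array(0, c(d, 3L))
  kH <- .HE_COLORS$hematoxylin * gains[[1]]
  kE <- .HE_COLORS$eosin * gains[[2]]
  for (c in 1:3)
    out[, , c] <- exp(-(kH[c] * nuclei + kE[c] * eosin))
  attr(out, "provenance") <- list(gains = gains)
  out
}
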