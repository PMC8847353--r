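## Ordinal 1-3 scoring of square ROIs on composition-positive maps, ROI
## placement, and rank-based ROC AUC.
##
## Rubrics (applied with precedence 3 -> 2 -> 1, which resolves the
## overlap between the written clauses):
##   vascular/lipid: 3 if pixels with count >= 2 make up at least 50% of
##     the valid ROI area; else 2 if any pixel has count >= 1; else 1.
##   nuclei: 3 if any pixel has count >= 2; else 2 if any pixel has
##     count >= 1; else 1.

## Pixel-index window of an ROI on a composition map.
.roi_window <- function(cmap, roi, spacing) {
  d <- dim(cmap@counts)
  i1 <- floor(roi@originMM[1] / spacing[1]) + 1L
  j1 <- floor(roi@originMM[2] / spacing[2]) + 1L
  ni <- max(1L, round(roi@sideMM / spacing[1]))
  nj <- max(1L, round(roi@sideMM / spacing[2]))
  .assert(i1 >= 1L && j1 >= 1L && i1 + ni - 1L <= d[1] &&
            j1 + nj - 1L <= d[2],
          "ROI extends outside the composition map")
  list(rows = i1:(i1 + ni - 1L), cols = j1:(j1 + nj - 1L))
}

.score_counts <- function(counts, valid, rubric) {
  .assert(sum(valid) >= 1L, "ROI has no valid pixels")
  .assert(sum(valid) / length(valid) >= 0.5,
          "ROI rejected: fewer than 50%% of its pixels are valid")
  cv <- counts[valid]
  frac_ge2 <- mean(cv >= 2L)
  frac_ge1 <- mean(cv >= 1L)
  score <- if (rubric == "vascular_lipid") {
    if (frac_ge2 >= 0.5) 3L else if (frac_ge1 > 0) 2L else 1L
  } else {
    if (any(cv >= 2L)) 3L else if (frac_ge1 > 0) 2L else 1L
  }
  list(score = score, fracGE2 = frac_ge2, fracGE1 = frac_ge1)
}

#' Score an ROI under the vascular/lipid rubric
#'
#' ROIs with no contrast score 1; presence of composition-positive pixels
#' (count 1 or 2) scores 2; pixels of count >= 2 composing at least 50% of
#' the valid ROI area score 3. ROIs with fewer than half their pixels
#' valid are rejected rather than silently scored.
#'
#' @param cmap a \linkS4class{CompositionMap}.
#' @param roi an \linkS4class{ROIBox} lying inside the map.
#' @param spacingMM in-plane pixel spacing (depth, lateral) of the map, mm.
#' @return A one-row data.frame: label, channel, rubric, score, and the
#'   supporting fractions of pixels with count >= 2 and >= 1.
#' @examples
#' cm <- compositionPositiveMap(rep(list(matrix(0, 20, 20)), 3))
#' scoreROIVascularLipid(cm, roiBox(c(0, 0), 0.5), c(0.05, 0.05))$score # 1
#' @export
scoreROIVascularLipid <- function(cmap, roi, spacingMM) {
  w <- .roi_window(cmap, roi, spacingMM)
  r <- .score_counts(cmap@counts[w$rows, w$cols],
                     cmap@valid[w$rows, w$cols], "vascular_lipid")
  data.frame(label = roi@label, channel = cmap@channel,
             rubric = "vascular_lipid", score = r$score,
             fracGE2 = r$fracGE2, fracGE1 = r$fracGE1)
}

#' Score an ROI under the nuclei rubric
#'
#' ROIs with no cellular content score 1; composition-positive pixels of
#' count 1 score 2; any pixel with count >= 2 scores 3.
#'
#' @inheritParams scoreROIVascularLipid
#' @return A one-row data.frame as in \code{\link{scoreROIVascularLipid}}.
#' @export
scoreROINuclei <- function(cmap, roi, spacingMM) {
  w <- .roi_window(cmap, roi, spacingMM)
  r <- .score_counts(cmap@counts[w$rows, w$cols],
                     cmap@valid[w$rows, w$cols], "nuclei")
  data.frame(label = roi@label, channel = cmap@channel, rubric = "nuclei",
             score = r$score, fracGE2 = r$fracGE2, fracGE1 = r$fracGE1)
}

#' Place cancerous and non-cancerous ROIs on a phantom slice
#'
#' Automates, for phantoms, what a pathologist does on real data: cancerous
#' ROIs are centred where the ground-truth label is carcinoma;
#' non-cancerous ROIs where the truth holds lipid, hemoglobin or nuclei
#' content without carcinoma. Boxes are non-overlapping and placement is
#' seed-reproducible.
#'
#' @param truthSlice integer label matrix (depth x lateral) of the truth
#'   plane the ROIs are scored against.
#' @param spacingMM pixel spacing of that plane (depth, lateral), mm.
#' @param nCancerous,nNonCancerous requested ROI counts (study layout:
#'   20 and 30).
#' @param sideMM ROI side length, mm (default 0.66).
#' @param seed placement seed.
#' @param maxTries rejection-sampling budget per ROI.
#' @param bestEffort if TRUE, return however many ROIs fit instead of
#'   erroring when the qualifying area cannot host the full request.
#' @return List of \linkS4class{ROIBox}; error (reporting the count
#'   achieved) if the qualifying area cannot host the request and
#'   \code{bestEffort} is FALSE.
#' @export
placeROIs <- function(truthSlice, spacingMM, nCancerous = 20L,
                      nNonCancerous = 30L, sideMM = 0.66, seed = 1L,
                      maxTries = 5000L, bestEffort = FALSE) {
  cls <- .PHANTOM_CLASSES
  d <- dim(truthSlice)
  ni <- max(1L, round(sideMM / spacingMM[1]))
  nj <- max(1L, round(sideMM / spacingMM[2]))
  .assert(d[1] >= ni && d[2] >= nj, "map too small for the ROI size")
  canc_ok <- truthSlice == cls[["carcinoma"]]
  noncanc_ok <- truthSlice %in% cls[c("adipose", "vessel", "duct_wall")] |
    truthSlice == cls[["stroma"]]
  if (nCancerous > 0L && !bestEffort)
    .assert(any(canc_ok),
            "no carcinoma in this truth plane: 0 of %d cancerous ROIs placed",
            nCancerous)
  .with_seed(seed, {
    placed <- list()
    taken <- matrix(FALSE, d[1], d[2])
    want <- c(rep("cancerous", nCancerous),
              rep("non_cancerous", nNonCancerous))
    for (k in seq_along(want)) {
      lab <- want[k]
      okmap <- if (lab == "cancerous") canc_ok else noncanc_ok
      done <- FALSE
      for (try in seq_len(maxTries)) {
        i1 <- sample.int(d[1] - ni + 1L, 1L)
        j1 <- sample.int(d[2] - nj + 1L, 1L)
        rows <- i1:(i1 + ni - 1L); cols <- j1:(j1 + nj - 1L)
        ctr <- okmap[i1 + ni %/% 2L, j1 + nj %/% 2L]
        if (!ctr) next
        if (any(taken[rows, cols])) next
        if (lab == "non_cancerous" && any(canc_ok[rows, cols])) next
        taken[rows, cols] <- TRUE
        placed[[length(placed) + 1L]] <- roiBox(c((i1 - 1L) * spacingMM[1],
                                                  (j1 - 1L) * spacingMM[2]),
                                                sideMM, lab)
        done <- TRUE
        break
      }
      if (!done && !bestEffort)
        stop(sprintf(
          "insufficient qualifying area: placed %d of %d requested ROIs",
          length(placed), length(want)), call. = FALSE)
    }
    placed
  })
}

#' Rank-based ROC AUC from ordinal ROI scores
#'
#' Mann-Whitney AUC: the probability a random positive-class score ranks
#' above a random negative-class score, ties counted one half — the
#' threshold-sweep ROC area coincides with this for ordinal data. The
#' polarity states whether a high score marks the positive (cancerous)
#' class; lipid and hemoglobin channels use \code{polarity = "low"}, since
#' low lipid marks cancerous tissue.
#'
#' @param scores numeric/ordinal scores, one per ROI.
#' @param labels class labels; \code{positive} names the positive class.
#' @param polarity \code{"high"} if larger scores indicate the positive
#'   class, \code{"low"} if smaller scores do.
#' @param positive label value treated as positive (default
#'   \code{"cancerous"}).
#' @return AUC in [0, 1].
#' @examples
#' aucFromScores(c(1, 1, 3, 3), c("cancerous", "cancerous",
#'                "non_cancerous", "non_cancerous"), polarity = "low") # 1
#' @export
aucFromScores <- function(scores, labels, polarity = c("high", "low"),
                          positive = "cancerous") {
  polarity <- match.arg(polarity)
  pos <- labels == positive
  .assert(any(pos) && any(!pos), "both classes must be present")
  s <- if (polarity == "low") -as.numeric(scores) else as.numeric(scores)
  r <- rank(s)  # average ranks on ties
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
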