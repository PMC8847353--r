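## Composition map with a given fraction of count-2 pixels inside a
## 30 x 30 map at 0.03 mm pixels; ROI covers a 22 x 22 window.
cmap_with_fraction <- function(frac2, seed = 1L) {
  set.seed(seed)
  s <- matrix(0, 30, 30)
  roi_px <- as.matrix(expand.grid(1:22, 1:22))
  n2 <- round(frac2 * nrow(roi_px))
  if (n2 > 0) {
    pick <- roi_px[sample.int(nrow(roi_px), n2), , drop = FALSE]
    s[pick] <- 1
  }
  compositionPositiveMap(list(s, s, 0 * s))   # selected pixels count 2
}

SP <- c(0.03, 0.03)
ROI <- roiBox(c(0, 0), 0.66)

test_that("vascular/lipid rubric scores follow the 1/2/3 precedence rules", {
  expect_identical(scoreROIVascularLipid(cmap_with_fraction(0), ROI, SP)$score,
                   1L)
  expect_identical(scoreROIVascularLipid(cmap_with_fraction(0.6), ROI,
                                         SP)$score, 3L)
  expect_identical(scoreROIVascularLipid(cmap_with_fraction(0.3), ROI,
                                         SP)$score, 2L)
  ## exactly 50% meets the score-3 clause
  expect_identical(scoreROIVascularLipid(cmap_with_fraction(0.5), ROI,
                                         SP)$score, 3L)
})

test_that("nuclei rubric scores on any count-2 pixel", {
  expect_identical(scoreROINuclei(cmap_with_fraction(0), ROI, SP)$score, 1L)
  one_px <- matrix(0, 30, 30); one_px[5, 5] <- 1
  cm <- compositionPositiveMap(list(one_px, one_px, 0 * one_px))
  expect_identical(scoreROINuclei(cm, ROI, SP)$score, 3L)
  cm1 <- compositionPositiveMap(list(one_px, 0 * one_px, 0 * one_px))
  expect_identical(scoreROINuclei(cm1, ROI, SP)$score, 2L)
})

test_that("both rubrics are monotone in pixel counts and agree at extremes", {
  set.seed(31)
  for (rep in 1:15) {
    counts <- matrix(sample(0:3, 900, replace = TRUE,
                            prob = c(0.6, 0.2, 0.1, 0.1)), 30, 30)
    slices <- lapply(1:3, function(k) (counts >= k) * 1)
    cm <- compositionPositiveMap(slices)
    sv <- scoreROIVascularLipid(cm, ROI, SP)$score
    sn <- scoreROINuclei(cm, ROI, SP)$score
    ## bump one in-ROI pixel to full count
    counts2 <- counts; counts2[3, 3] <- 3
    cm2 <- compositionPositiveMap(lapply(1:3, function(k) (counts2 >= k) * 1))
    expect_gte(scoreROIVascularLipid(cm2, ROI, SP)$score, sv)
    expect_gte(scoreROINuclei(cm2, ROI, SP)$score, sn)
  }
  all3 <- compositionPositiveMap(rep(list(matrix(1, 30, 30)), 3))
  expect_identical(scoreROIVascularLipid(all3, ROI, SP)$score, 3L)
  expect_identical(scoreROINuclei(all3, ROI, SP)$score, 3L)
  expect_error(scoreROINuclei(cmap_with_fraction(0), roiBox(c(0.5, 0.5)),
                              SP), "outside")
})

test_that("ROI placement is label-faithful, non-overlapping, reproducible", {
  ## constructed truth plane with ample carcinoma and adipose area
  plane <- matrix(2L, 150, 260)
  plane[, 1:120] <- 5L                # carcinoma
  plane[, 140:260] <- 1L              # adipose
  rois <- placeROIs(plane, c(0.03, 0.03), 20, 30, sideMM = 0.45, seed = 9)
  expect_length(rois, 50)
  labs <- vapply(rois, function(b) b@label, character(1))
  expect_identical(sum(labs == "cancerous"), 20L)
  ## label audit: box centers carry the truth class they claim
  for (b in rois) {
    ctr <- floor((b@originMM + b@sideMM / 2) / 0.03) + 1L
    if (b@label == "cancerous")
      expect_identical(plane[ctr[1], ctr[2]], 5L)
    else expect_true(plane[ctr[1], ctr[2]] %in% c(1L, 2L))
  }
  ## non-overlap audit
  px <- matrix(FALSE, 150, 260)
  for (b in rois) {
    i <- floor(b@originMM[1] / 0.03) + seq_len(15)
    j <- floor(b@originMM[2] / 0.03) + seq_len(15)
    expect_false(any(px[i, j]))
    px[i, j] <- TRUE
  }
  rois2 <- placeROIs(plane, c(0.03, 0.03), 20, 30, sideMM = 0.45, seed = 9)
  expect_identical(lapply(rois, function(b) b@originMM),
                   lapply(rois2, function(b) b@originMM))

  no_canc <- matrix(2L, 60, 60)
  expect_error(placeROIs(no_canc, c(0.03, 0.03), 5, 0, sideMM = 0.45),
               "no carcinoma")
})

test_that("rank AUC matches the all-pairs oracle and handles polarity", {
  expect_equal(aucFromScores(c(2, 2, 2, 2), c("cancerous", "cancerous",
               "non_cancerous", "non_cancerous")), 0.5)
  expect_equal(aucFromScores(c(1, 1, 3, 3, 3),
                             c("cancerous", "cancerous", rep("non_cancerous", 3)),
                             polarity = "low"), 1.0)
  expect_error(aucFromScores(c(1, 2), c("cancerous", "cancerous")),
               "both classes")

  set.seed(17)
  for (rep in 1:50) {
    sc <- sample(1:3, 6, replace = TRUE)
    lb <- sample(rep(c("cancerous", "non_cancerous"), 3))
    for (pol in c("high", "low")) {
      expect_equal(aucFromScores(sc, lb, polarity = pol),
                   auc_brute_force(sc, lb, polarity = pol))
    }
  }
})
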