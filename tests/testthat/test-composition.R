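test_that("composition-positive maps count positive slices per pixel", {
  zeroes <- rep(list(matrix(0, 4, 4)), 3)
  expect_true(all(countMap(compositionPositiveMap(zeroes)) == 0L))

  s1 <- matrix(0, 3, 3); s1[2, 2] <- 1
  s2 <- matrix(0, 3, 3)
  s3 <- matrix(0, 3, 3); s3[2, 2] <- 1
  cm <- compositionPositiveMap(list(s1, s2, s3))
  expect_identical(countMap(cm)[2, 2], 2L)
  expect_identical(sum(countMap(cm)), 2L)

  expect_error(compositionPositiveMap(list(matrix(0, 2, 2),
                                           matrix(0, 3, 3))), "differ")
  expect_error(compositionPositiveMap(list()), "at least one")
})

test_that("composition maps equal the per-pixel loop oracle", {
  set.seed(21)
  for (rep in 1:20) {
    slices <- lapply(1:3, function(i)
      matrix(rbinom(48, 1, runif(1, 0.2, 0.8)), 6, 8))
    cm <- compositionPositiveMap(slices)
    expect_identical(countMap(cm), composition_loop_sum(slices))
    ## sum form and average form agree exactly
    expect_identical(fractionMap(cm), countMap(cm) / 3)
  }
})

test_that("mean fraction over the mask equals pooled percent / 100", {
  set.seed(3)
  slices <- lapply(1:3, function(i) matrix(rbinom(100, 1, 0.4), 10, 10))
  cm <- compositionPositiveMap(slices)
  ## per-slice percent pooled with equal valid areas
  per_slice <- vapply(slices, function(s) 100 * mean(s), numeric(1))
  expect_equal(mean(fractionMap(cm)), mean(per_slice) / 100,
               tolerance = 1e-12)
  ## slice order is irrelevant
  cm2 <- compositionPositiveMap(rev(slices))
  expect_identical(countMap(cm), countMap(cm2))
})

test_that("tissue mask recovers the phantom block and is connected", {
  ph <- small_phantom()
  us <- ph$anterior$ultrasound
  mask <- tissueMask(us)
  truth_mask <- patquant:::.resample3_nn(
    ph$truth@tissue * 1L, ph$truth@spacingMM, spacingMM(us),
    dim(voxelData(us))) == 1L
  dice <- 2 * sum(mask & truth_mask) / (sum(mask) + sum(truth_mask))
  expect_gt(dice, 0.9)
  ## each tissue-bearing slice yields one connected component
  mid <- dim(mask)[1] %/% 2
  lab <- EBImage::bwlabel(mask[mid, , ] * 1)
  expect_equal(max(lab), 1)
  expect_error(tissueMask(array(0, c(2, 5, 5))), "constant|foreground")
})

test_that("percent composition uses the valid in-mask denominator", {
  mask <- array(FALSE, c(1, 6, 6)); mask[1, 2:5, 2:5] <- TRUE
  bin <- array(0L, c(1, 6, 6)); bin[mask] <- 1L
  expect_equal(percentComposition(bin, mask), 100)
  expect_equal(percentComposition(array(0L, c(1, 6, 6)), mask), 0)
  expect_error(percentComposition(bin, array(FALSE, c(1, 6, 6))),
               "zero valid")
  ## excluded pixels drop from numerator and denominator
  bv <- averageAndApply(0.5, array(1, c(1, 6, 6)),
                        artifactMask = !mask)
  expect_equal(percentComposition(bv, mask), 100)
})

test_that("pipeline bookkeeping audits regions and image counts", {
  std <- regionPipelineCounts(3, 5, 3)
  expect_identical(std$totalRegions, 15)
  expect_identical(std$totalImages, 45)
  expect_identical(regionPipelineCounts(1, 1, 3)$totalImages, 3)
  expect_identical(regionPipelineCounts(2, 5, 3)$totalRegions, 10)
  expect_identical(regionPipelineCounts(2, 5, 3)$totalImages, 30)
  ## config-list form
  cfg <- list(samples = list("a", "b", "c"), regions_per_sample = 5,
              slices_per_region = 3)
  expect_identical(regionPipelineCounts(cfg)$totalImages, 45)
})
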