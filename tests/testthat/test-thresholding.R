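test_that("Otsu separates a two-level image exactly and shifts with it", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  t0 <- otsuThreshold(img)
  expect_gt(t0, 10); expect_lte(t0, 200)
  expect_identical(img > t0, img == 200)

  set.seed(1)
  base <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  bin_w <- diff(range(base)) / 256
  expect_lt(abs(otsuThreshold(base + 40) - (otsuThreshold(base) + 40)),
            2 * bin_w)
  expect_error(otsuThreshold(matrix(5, 3, 3)), "constant")
})

test_that("Otsu agrees with the exhaustive between-class-variance search", {
  set.seed(123)
  for (i in 1:30) {
    ## mixtures give structured histograms; plain uniform also covered
    v <- if (i %% 2 == 0) {
      c(rnorm(300, 60, 20), rnorm(200, 180, 25))
    } else runif(512, 0, 255)
    v <- pmin(pmax(round(v), 0), 255)
    img <- matrix(v[1:256], 16, 16)
    t_pkg <- otsuThreshold(img)
    t_ref <- otsu_brute_force(img)
    expect_identical(img > t_pkg, img > t_ref)
  }
})

test_that("histogram valley threshold splits two modes, falls back when unimodal", {
  set.seed(5)
  v <- c(rnorm(1500, 30, 10), rnorm(1500, 180, 10))
  th <- histogramRegionThreshold(v)
  expect_gt(th, 80); expect_lt(th, 130)

  ## mode frequencies swapped: threshold still lies between the modes
  v2 <- c(rnorm(500, 30, 10), rnorm(2500, 180, 10))
  th2 <- histogramRegionThreshold(v2)
  expect_gt(th2, 80); expect_lt(th2, 130)

  uni <- rnorm(2000, 100, 15)
  expect_warning(thu <- histogramRegionThreshold(uni), "unimodal")
  expect_equal(thu, unname(quantile(uni, 0.95)))
  expect_error(histogramRegionThreshold(rep(3, 100)), "constant")
})

test_that("threshold averaging and masking binarize as specified", {
  img <- array(c(rep(10, 8), rep(200, 8)), c(1, 4, 4))
  b <- averageAndApply(100, img)
  expect_identical(sum(voxelData(b)), 8L)
  expect_identical(voxelData(b)[1, , ] == 1L, img[1, , ] == 200)

  b2 <- averageAndApply(c(90, 110), img)
  expect_equal(b2@appliedThreshold, 100)

  mask <- array(TRUE, dim(img))
  b3 <- averageAndApply(100, img, artifactMask = mask)
  expect_true(all(voxelData(b3) == 0L))
  expect_equal(mean(excludedMask(b3)), 1)
  expect_error(averageAndApply(numeric(0), img), "empty")
})

test_that("binarization is monotone in the threshold", {
  set.seed(9)
  img <- array(runif(200), c(2, 10, 10))
  lower <- voxelData(averageAndApply(0.3, img))
  higher <- voxelData(averageAndApply(0.6, img))
  expect_true(all(higher <= lower))
})
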