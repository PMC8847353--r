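test_that("medianStack computes robust per-pixel medians", {
  f <- matrix(runif(20), 4, 5)
  expect_identical(medianStack(rep(list(f), 10)), f)

  frames <- lapply(c(1:9, 1000), function(v) matrix(v, 2, 2))
  expect_identical(medianStack(frames), matrix(5.5, 2, 2))

  ## median of 10 noisy frames beats a single frame
  set.seed(42)
  noisy <- lapply(1:10, function(i) matrix(50 + rnorm(900, sd = 10), 30, 30))
  med <- medianStack(noisy)
  expect_lt(sd(med - 50), sd(noisy[[1]] - 50))

  ## permutation invariance and shape guard
  expect_identical(medianStack(noisy), medianStack(rev(noisy)))
  expect_error(medianStack(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape")
})

test_that("depth cropping measures from the imaged surface", {
  arr <- array(runif(3 * 60 * 4), c(3, 60, 4))
  vol <- channelVolume(arr, c(0.193, 0.05, 0.1), "pat_lipid")
  expect_identical(dim(voxelData(cropToDepth(vol, 2.0)))[2], 40L)
  expect_identical(voxelData(cropToDepth(vol, 3.0)), arr)  # full extent
  expect_error(cropToDepth(vol, 3.5), "exceeds")
  ## idempotence
  once <- cropToDepth(vol, 1.5)
  expect_identical(voxelData(cropToDepth(once, 1.5)), voxelData(once))

  ## posterior volumes use the same convention, so flip-then-crop on raw
  ## data equals crop-then-flip: check on a depth ramp
  ramp <- array(as.numeric(1:60), c(1, 60, 1))
  flip <- ramp[, 60:1, , drop = FALSE]
  post <- channelVolume(flip, c(0.193, 0.05, 0.1), "pat_lipid",
                        side = "posterior")
  cropped <- voxelData(cropToDepth(post, 1.0))       # 20 px from surface
  expect_identical(as.vector(cropped), as.numeric(60:41))
})

test_that("local contrast enhancement amplifies detail, preserves edges, clips", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_identical(localContrastEnhance(img, 0), img)
  flat <- matrix(3.2, 32, 32)
  expect_identical(localContrastEnhance(flat, 2), flat)
  expect_error(localContrastEnhance(matrix(c(1, NA, 2, 3), 2)), "finite")

  ## step edge with fine texture: texture variance grows, edge stays put
  set.seed(7)
  step <- matrix(rep(c(0.2, 0.8), each = 32), 64, 64, byrow = FALSE)
  tex <- step + matrix(rnorm(64 * 64, sd = 0.03), 64, 64)
  out <- localContrastEnhance(tex, 1, edgeThreshold = 0.2)
  in_block <- 5:28  ## texture away from the edge
  expect_gt(var(as.vector(out[in_block, ])), var(as.vector(tex[in_block, ])))
  grad_in <- apply(tex, 2, function(col) which.max(abs(diff(col))))
  grad_out <- apply(out, 2, function(col) which.max(abs(diff(col))))
  expect_identical(grad_in, grad_out)

  ## clipping contract on random images
  for (s in 1:5) {
    set.seed(s)
    im <- matrix(rnorm(400), 20, 20)
    o <- localContrastEnhance(im, 3)
    expect_gte(min(o), min(im)); expect_lte(max(o), max(im))
  }
})

test_that("NCC slice matching recovers known correspondences", {
  set.seed(11)
  vol <- array(runif(10 * 16 * 16), c(10, 16, 16))
  id <- matchSlicesNCC(vol, vol)
  expect_identical(id$sliceB, id$sliceA)

  shifted <- vol[c(3:10, 1:2), , ]   # B = A shifted by 2 slices
  m <- matchSlicesNCC(shifted, vol, coarseMap = pmin(seq_len(10) + 2, 10),
                      window = 2)
  expect_identical(m$sliceB[1:8], m$sliceA[1:8] + 2L)
  expect_false(is.unsorted(m$sliceB))

  ## phantom PAT lipid vs lipid-weighted (inverted eosin) light sheet:
  ## correspondence recovered within one slice
  ph <- small_phantom()
  pat <- voxelData(ph$anterior$pat_lipid)
  eos <- ph$anterior$ispim_eosin
  d <- dim(pat)
  eosd <- patquant:::.resample3(voxelData(eos), spacingMM(eos),
                                spacingMM(ph$anterior$pat_lipid), d)
  eosd <- max(eosd) - eosd      # eosin-dim = lipid-rich
  mm <- matchSlicesNCC(pat, eosd, window = 2)
  expect_true(all(abs(mm$sliceB - mm$sliceA) <= 1))
})
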