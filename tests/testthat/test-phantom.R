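test_that("phantom generation is seed-deterministic and honors class targets", {
  p <- small_params(seed = 1L)
  a <- generatePhantom(p, sides = "anterior", channels = "pat_lipid")
  b <- generatePhantom(p, sides = "anterior", channels = "pat_lipid")
  expect_identical(a$truth@labels, b$truth@labels)
  expect_identical(a$truth@nuclei, b$truth@nuclei)
  expect_identical(voxelData(a$anterior$pat_lipid),
                   voxelData(b$anterior$pat_lipid))

  fr <- classFractions(a$truth)
  expect_gte(fr[["adipose"]], 0.8 * 0.30)   # within 20% relative of target
  expect_lte(fr[["adipose"]], 1.2 * 0.30)

  no_ca <- generatePhantom(
    small_params(seed = 1L, fractions = c(adipose = 0.3, duct = 0.04,
                                          carcinoma = 0, vessel = 0.02)),
    sides = "anterior", channels = "pat_lipid")
  expect_identical(sum(no_ca$truth@labels == 5L), 0L)
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantomParams(fractions = c(adipose = 0.7, duct = 0.2,
                                           carcinoma = 0.2, vessel = 0.1)),
               "sum")
  expect_error(
    generatePhantom(phantomParams(extentMM = c(0.6, 0.6, 0.6),
                                  carcinomaRadiusMM = c(0.5, 0.6),
                                  marginMM = 0.1, seed = 1),
                    sides = "anterior", channels = "pat_lipid"),
    "too small")
})

test_that("PAT rendering follows the exponential fluence decay", {
  ## hemoglobin slab spanning the full depth of a hand-built truth
  d <- c(20L, 60L, 20L)               # 0.4 x 1.2 x 0.4 mm at 0.02 mm
  labels <- array(2L, d)
  labels[8:13, , 8:13] <- 6L          # vessel column along depth
  truth <- make_truth(labels)
  p <- phantomParams(extentMM = d * 0.02, fluenceDecayMM = 1,
                     patBlurSigmaMM = c(0.02, 0.01, 0.02),
                     noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                 pat_off = 0, ultrasound = 0,
                                 ispim_eosin = 0, ispim_nuclei = 0),
                     seed = 1)
  vol <- renderPATChannel(truth, "hemoglobin", p)
  arr <- voxelData(vol)
  sp <- spacingMM(vol)
  core <- round(c(0.20, 0.22) / sp[3])          # lateral center of vessel
  depth_px <- function(mm) max(1L, round(mm / sp[2]))
  surf <- mean(arr[, depth_px(0.05), core[1]:core[2]])
  deep <- mean(arr[, depth_px(1.05), core[1]:core[2]])
  expected <- exp(-(1.05 - 0.05) / 1)
  expect_equal(deep / surf, expected, tolerance = 0.08)

  ## off-resonance with zero noise renders an all-zero volume
  off <- renderPATChannel(truth, "off_resonance", p)
  expect_true(all(voxelData(off) == 0))
})

test_that("noiseless lipid render tracks the lipid concentration", {
  p <- small_params(seed = 3L,
                    noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                pat_off = 0, ultrasound = 0,
                                ispim_eosin = 0, ispim_nuclei = 0),
                    fluenceDecayMM = 1e6)
  ph <- generatePhantom(p, sides = "anterior", channels = "pat_lipid")
  arr <- voxelData(ph$anterior$pat_lipid)
  conc <- patquant:::.resample3(ph$truth@lipid, ph$truth@spacingMM,
                                p@patSpacingMM, dim(arr))
  conc <- patquant:::.gauss_blur3(conc, p@patBlurSigmaMM / p@patSpacingMM)
  expect_gt(cor(as.vector(arr), as.vector(conc)), 0.99)
})

test_that("anterior and posterior views mirror the same truth", {
  d <- c(10L, 40L, 10L)
  labels <- array(2L, d)
  labels[4:7, 11:30, 4:7] <- 1L  # lipid block, symmetric about mid-depth
  truth <- make_truth(labels)
  p <- phantomParams(extentMM = d * 0.02, fluenceDecayMM = 1.5,
                     patSpacingMM = c(0.1, 0.02, 0.1),
                     patBlurSigmaMM = c(0.02, 0.02, 0.02),
                     noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                 pat_off = 0, ultrasound = 0,
                                 ispim_eosin = 0, ispim_nuclei = 0),
                     seed = 1)
  ant <- voxelData(renderPATChannel(truth, "lipid", p, "anterior"))
  post <- voxelData(renderPATChannel(truth, "lipid", p, "posterior"))
  ## each side measures depth from its own surface, so a depth-symmetric
  ## phantom yields identical renders in those frames (mirror images in
  ## laboratory coordinates)
  expect_equal(ant, post, tolerance = 1e-8)
})

test_that("nuclei channel renders one resolvable spot per nucleus", {
  d <- c(30L, 30L, 30L)
  labels <- array(2L, d)
  ## 100 nuclei on a well-separated grid of voxel centres (0.1 mm pitch)
  at_center <- function(i) (i - 0.5) * 0.02
  grid <- as.matrix(expand.grid(x = at_center(c(5, 10, 15, 20, 25)),
                                y = at_center(c(5, 10, 15, 20, 25)),
                                z = at_center(c(6, 12, 18, 24))))
  truth <- make_truth(labels, nuclei = grid)
  p <- phantomParams(extentMM = d * 0.02, stripeAmplitude = 0,
                     ispimSpacingMM = rep(0.02, 3),
                     noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                 pat_off = 0, ultrasound = 0,
                                 ispim_eosin = 0, ispim_nuclei = 0),
                     seed = 1)
  nuc <- renderISPIMChannels(truth, p, which = "nuclei")
  expect_identical(count_local_maxima(voxelData(nuc), 0.5), 100L)

  ## empty nuclei set with zero noise renders an empty channel
  empty <- renderISPIMChannels(make_truth(labels), p, which = "nuclei")
  expect_true(all(voxelData(empty) == 0))
})

test_that("eosin channel is flat on uniform stroma without stripes", {
  d <- c(10L, 20L, 40L)
  truth <- make_truth(array(2L, d))
  p <- phantomParams(extentMM = d * 0.02, stripeAmplitude = 0,
                     ispimSpacingMM = rep(0.02, 3),
                     noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                 pat_off = 0, ultrasound = 0,
                                 ispim_eosin = 0, ispim_nuclei = 0),
                     seed = 1)
  eos <- voxelData(renderISPIMChannels(truth, p, which = "eosin"))
  col_means <- apply(eos, 3, mean)
  expect_lt(diff(range(col_means)), 1e-12)

  ## with stripes on, column means oscillate
  p2 <- phantomParams(extentMM = d * 0.02, stripeAmplitude = 0.2,
                      ispimSpacingMM = rep(0.02, 3),
                      noiseSD = p@noiseSD, seed = 1)
  eos2 <- voxelData(renderISPIMChannels(truth, p2, which = "eosin"))
  expect_gt(diff(range(apply(eos2, 3, mean))), 0.1)
})

test_that("ultrasound render is piecewise constant without speckle", {
  ph <- small_phantom()
  p0 <- small_params(seed = 4L,
                     noiseSD = c(pat_lipid = 0, pat_hemoglobin = 0,
                                 pat_off = 0, ultrasound = 0,
                                 ispim_eosin = 0, ispim_nuclei = 0))
  us <- renderUltrasound(ph$truth, p0)
  arr <- voxelData(us)
  expect_lte(length(unique(as.vector(arr))), 7L)  # one level per class
  ## background voxels are exactly zero
  labp <- patquant:::.resample3_nn(ph$truth@labels, ph$truth@spacingMM,
                                   p0@patSpacingMM, dim(arr))
  expect_true(all(arr[labp == 0L] == 0))
  ## duct lumina are hypoechoic relative to stroma
  if (any(labp == 3L))
    expect_lt(mean(arr[labp == 3L]), mean(arr[labp == 2L]))
})
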