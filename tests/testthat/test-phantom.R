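# Phantom generator and noise models: determinism, structure, and the
# calibration of the speckle / AWGN corruption models.

test_that("phantom with no structure requested is constant", {
  spec <- PhantomSpec(32, 32, nLesions = 0, backgroundLevel = 128,
                      textureScale = Inf, seed = 0)
  img <- generatePhantom(spec)
  expect_equal(dim(img), c(32L, 32L))
  expect_true(all(img == 128))
})

test_that("phantom generation is deterministic for a fixed seed", {
  spec <- PhantomSpec(48, 48, nLesions = 3, seed = 42)
  expect_identical(generatePhantom(spec), generatePhantom(spec))
  spec2 <- PhantomSpec(48, 48, nLesions = 3, seed = 43)
  expect_false(identical(generatePhantom(spec), generatePhantom(spec2)))
})

test_that("lesions create a second histogram mode near background + contrast", {
  spec <- PhantomSpec(64, 64, nLesions = 2, backgroundLevel = 120,
                      lesionContrast = 60, textureScale = 8, seed = 7)
  img <- generatePhantom(spec)
  nearBg <- mean(abs(img - 120) <= 15)
  nearLesion <- mean(abs(img - 180) <= 15)
  expect_gt(nearBg, 0.4)         # background mode dominates
  expect_gt(nearLesion, 0.02)    # lesion mode present
  # modes separated by the full contrast: almost no mass in between
  expect_lt(mean(img > 140 & img < 160), nearLesion + nearBg)
})

test_that("invalid phantom specs are rejected", {
  expect_error(PhantomSpec(0, 32), "height")
  expect_error(PhantomSpec(32, 32, backgroundLevel = 220,
                           lesionContrast = 60), "within")
  expect_error(PhantomSpec(32, 32, nLesions = -1), "nLesions")
})

test_that("speckle with infinite looks is the identity", {
  img <- tinyPhantom(1)
  expect_identical(addSpeckle(img, NoiseSpec("speckle", looks = Inf)), img)
})

test_that("speckle field has unit mean and variance 1/looks", {
  img <- matrix(100, 256, 256)
  for (L in c(1, 4, 16)) {
    noisy <- addSpeckle(img, NoiseSpec("speckle", looks = L, seed = L))
    field <- noisy / 100
    n <- length(field)
    # tolerance: three standard errors of each sample moment
    seMean <- sqrt(1 / L / n)
    expect_lt(abs(mean(field) - 1), 3 * seMean)
    # SE of the sample variance for a Gamma(L, L) field (kurtosis 6/L)
    seVar <- sqrt((2 + 6 / L) / n) / L
    expect_lt(abs(var(as.vector(field)) - 1 / L), 3 * seVar)
  }
  # looks = 4, constant 100: output variance within 5% of 100^2 / 4
  noisy <- addSpeckle(img, NoiseSpec("speckle", looks = 4, seed = 0))
  expect_lt(abs(var(as.vector(noisy)) - 2500) / 2500, 0.05)
})

test_that("speckle rejects non-positive looks and wrong kind", {
  img <- tinyPhantom(1)
  expect_error(NoiseSpec("speckle", looks = 0), "looks")
  expect_error(addSpeckle(img, NoiseSpec("awgn", snrDb = 25)), "speckle")
})

test_that("awgn hits its target SNR and handles limits", {
  img <- generatePhantom(PhantomSpec(256, 256, seed = 5))
  for (target in c(0, 25, 45)) {
    noisy <- addAwgnAtSnr(img, NoiseSpec("awgn", snrDb = target,
                                         seed = target + 1))
    expect_lt(abs(snrDb(img, noisy) - target), 0.5)
  }
  expect_identical(addAwgnAtSnr(img, NoiseSpec("awgn", snrDb = Inf)), img)
  expect_error(addAwgnAtSnr(matrix(0, 8, 8), NoiseSpec("awgn", snrDb = 25)),
               "all-zero")
})

test_that("awgn at 0 dB on a constant image has noise sd equal to the level", {
  img <- matrix(100, 128, 128)
  noisy <- addAwgnAtSnr(img, NoiseSpec("awgn", snrDb = 0, seed = 9))
  expect_lt(abs(sd(as.vector(noisy - img)) - 100) / 100, 0.05)
})

test_that("makeDataset produces disjoint reproducible splits", {
  spec <- PhantomSpec(32, 32, nLesions = 1, textureScale = 4)
  ns <- NoiseSpec("speckle", looks = 4)
  ds1 <- makeDataset(4, 2, spec, ns, seed = 3)
  ds2 <- makeDataset(4, 2, spec, ns, seed = 3)
  expect_length(ds1$train, 4)
  expect_length(ds1$test, 2)
  expect_identical(ds1, ds2)
  # all clean images pairwise distinct
  all6 <- c(lapply(ds1$train, `[[`, "clean"), lapply(ds1$test, `[[`, "clean"))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_false(identical(all6[[i]], all6[[j]]))
    }
  }
  # corruption actually applied
  expect_false(identical(ds1$train[[1]]$clean, ds1$train[[1]]$noisy))
})
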