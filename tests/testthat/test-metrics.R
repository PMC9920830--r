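# Image-quality metrics: closed-form values, brute-force oracles,
# invariances, and report serialization.

test_that("mse matches a double-loop reference", {
  a <- randomImage(12, seed = 1)
  b <- randomImage(12, seed = 2)
  expect_equal(mseImage(a, a), 0)
  expect_equal(mseImage(a, a + 3), 9)
  ref <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      ref <- ref + (a[i, j] - b[i, j])^2
    }
  }
  expect_lt(abs(mseImage(a, b) - ref / length(a)), 1e-10)
  expect_error(mseImage(a, randomImage(8)), "shape")
})

test_that("psnr closed forms hold", {
  # mse = 255^2 gives exactly 0 dB
  expect_equal(psnr(matrix(0, 4, 4), matrix(255, 4, 4)), 0)
  # mse = 1 gives 10*log10(65025)
  a <- matrix(0, 4, 4)
  expect_equal(psnr(a, a + 1), 10 * log10(65025))
  expect_identical(psnr(a, a), Inf)
})

test_that("snr closed forms and errors hold", {
  ref <- matrix(100, 8, 8)
  expect_equal(snrDb(ref, ref + 10), 20)
  expect_identical(snrDb(ref, ref), Inf)
  expect_error(snrDb(matrix(0, 4, 4), matrix(1, 4, 4)), "zero power")
})

test_that("psnr equals snr plus the peak-to-signal-power offset", {
  a <- tinyPhantom(3)
  b <- addSpeckle(a, NoiseSpec("speckle", looks = 4, seed = 4))
  expect_equal(psnr(a, b), snrDb(a, b) + 10 * log10(255^2 / mean(a^2)))
})

test_that("epi is a bounded correlation with the expected fixed points", {
  img <- tinyPhantom(5)
  expect_equal(epi(img, img), 1)
  expect_equal(epi(img, -img), -1)
  withr::with_seed(0, {
    noisy <- img + matrix(rnorm(length(img), sd = 10), nrow(img), ncol(img))
  })
  e <- epi(img, noisy)
  expect_gt(e, 0)
  expect_lt(e, 1)
  expect_error(epi(matrix(5, nrow(img), ncol(img)), img),
               "constant Laplacian")
})

test_that("epi is invariant to constant shifts and joint positive rescaling", {
  a <- tinyPhantom(6)
  b <- addSpeckle(a, NoiseSpec("speckle", looks = 8, seed = 7))
  e <- epi(a, b)
  expect_equal(epi(a + 17, b), e)
  expect_equal(epi(a, b - 5), e)
  expect_equal(epi(2.5 * a, 2.5 * b), e)
})

test_that("false recognition rate counts tolerance exceedances", {
  a <- matrix(50, 8, 8)
  expect_equal(falseRecognitionRate(a, a), 0)
  expect_equal(falseRecognitionRate(a + 10, a, tolGray = 5), 1)
  half <- a
  half[, 1:4] <- half[, 1:4] + 10
  expect_equal(falseRecognitionRate(half, a, tolGray = 5), 0.5)
})

test_that("destruction time sums stage times", {
  expect_equal(destructionTime(numeric()), 0)
  expect_equal(destructionTime(c(1.5, 2.5)), 4)
  expect_equal(destructionTime(c(2.5, 1.5)), destructionTime(c(1.5, 2.5)))
  expect_error(destructionTime(c(1, -0.1)), "non-negative")
})

test_that("evaluateDenoising fills every report field coherently", {
  clean <- tinyPhantom(8)
  noisy <- addSpeckle(clean, NoiseSpec("speckle", looks = 4, seed = 9))
  perfect <- evaluateDenoising(clean, noisy, clean, stageTimes = c(0.5, 0.5))
  expect_s4_class(perfect, "EvalReport")
  expect_equal(perfect@mse, 0)
  expect_identical(perfect@psnrDb, Inf)
  expect_equal(perfect@epi, 1)
  expect_equal(perfect@falseRecognitionRate, 0)
  expect_equal(perfect@tDes, 1)
  # the no-op "denoiser" just reproduces the noisy baseline
  noop <- evaluateDenoising(clean, noisy, noisy)
  expect_equal(noop@mse, mseImage(noisy, clean))
  expect_equal(noop@psnrDb, psnr(clean, noisy))
  expect_lt(noop@epi, 0.5)
})

test_that("evaluation reports round-trip through JSON losslessly", {
  clean <- tinyPhantom(9)
  noisy <- addSpeckle(clean, NoiseSpec("speckle", looks = 4, seed = 10))
  for (denoised in list(noisy, clean)) {  # finite and infinite PSNR
    rep1 <- evaluateDenoising(clean, noisy, denoised, stageTimes = 1.25)
    path <- withr::local_tempfile(fileext = ".json")
    writeReport(rep1, path)
    rep2 <- readReport(path)
    expect_equal(reportAsList(rep2), reportAsList(rep1))
  }
})
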