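# Guided filter (fast vs explicit-kernel oracle), detail enhancement,
# high-pass correction, and the chained preprocessing pipeline.

test_that("guided filter leaves constant inputs unchanged", {
  guide <- randomImage(16, seed = 1)
  const <- matrix(42, 16, 16)
  out <- guidedFilter(const, guide, GuidedFilterParams())
  expect_equal(out, const, tolerance = 1e-12)
})

test_that("guided filter degenerates to a double box filter as epsilon grows", {
  img <- randomImage(16, seed = 2)
  r <- 2L
  out <- guidedFilter(img, img, GuidedFilterParams(radius = r,
                                                  epsilon = 1e8))
  N <- despeckle:::boxCount(16, 16, r)
  twiceBox <- despeckle:::boxSum(despeckle:::boxSum(img, r) / N, r) / N
  expect_equal(out, twiceBox, tolerance = 1e-6)
})

test_that("fast guided filter matches the explicit kernel oracle", {
  p <- GuidedFilterParams(radius = 2, epsilon = 0.01)
  for (s in 1:10) {
    img <- randomImage(16, seed = s)
    expect_lt(max(abs(guidedFilter(img, img, p) -
                      guidedFilterBruteForce(img, img, p))), 1e-8)
  }
  # and with guide distinct from input
  a <- randomImage(12, seed = 21)
  g <- randomImage(12, seed = 22)
  expect_lt(max(abs(guidedFilter(a, g, p) -
                    guidedFilterBruteForce(a, g, p))), 1e-8)
})

test_that("guided-filter kernel rows sum to one", {
  img <- randomImage(10, seed = 3)
  W <- guidedFilterKernel(img, GuidedFilterParams(radius = 2,
                                                  epsilon = 0.05))
  expect_equal(rowSums(W), rep(1, 100), tolerance = 1e-10)
})

test_that("self-guided filtering does not increase total variation", {
  for (s in 1:5) {
    noisy <- addSpeckle(tinyPhantom(s),
                        NoiseSpec("speckle", looks = 4, seed = s))
    sm <- guidedFilter(noisy, noisy, GuidedFilterParams(radius = 2,
                                                        epsilon = 0.01))
    expect_lte(totalVariation(sm), totalVariation(noisy))
  }
})

test_that("guided filter rejects mismatched shapes and oversized windows", {
  expect_error(guidedFilter(randomImage(8), randomImage(10)), "shape")
  expect_error(guidedFilter(randomImage(4), randomImage(4),
                            GuidedFilterParams(radius = 3)), "window")
})

test_that("detailEnhance is exact at gains 0 and 1 and linear in the gain", {
  orig <- randomImage(8, seed = 4)
  base <- randomImage(8, seed = 5)
  expect_identical(detailEnhance(orig, base, 1), orig)
  expect_identical(detailEnhance(orig, base, 0), base)
  expect_equal(detailEnhance(matrix(100, 8, 8), matrix(90, 8, 8), 2),
               matrix(110, 8, 8))
  g1 <- detailEnhance(orig, base, 1.5) - base
  g2 <- detailEnhance(orig, base, 3) - base
  expect_equal(g2, 2 * g1)
})

test_that("high-pass kernel has the published coefficients", {
  expect_equal(highpassKernel() * 17,
               matrix(c(-2, -1, -2, -1, 18, -1, -2, -1, -2), 3, 3,
                      byrow = TRUE))
  expect_equal(sum(highpassKernel()), 6 / 17)
})

test_that("high-pass filter maps constant 17 to constant 6", {
  expect_equal(highpassFilter(matrix(17, 9, 9)), matrix(6, 9, 9))
})

test_that("high-pass impulse response reproduces the kernel", {
  img <- matrix(0, 9, 9)
  img[5, 5] <- 17
  out <- highpassFilter(img)
  expect_equal(out[4:6, 4:6], highpassKernel() * 17)
  expect_true(all(out[-(4:6), -(4:6)] == 0))
})

test_that("high-pass filter is linear and shift-equivariant off the border", {
  a <- randomImage(16, seed = 6)
  b <- randomImage(16, seed = 7)
  expect_equal(highpassFilter(2 * a + 3 * b),
               2 * highpassFilter(a) + 3 * highpassFilter(b))
  shifted <- matrix(0, 16, 16)
  shifted[2:16, ] <- a[1:15, ]
  expect_equal(highpassFilter(shifted)[3:15, 2:15],
               highpassFilter(a)[2:14, 2:15])
  expect_error(highpassFilter(matrix(1, 2, 2)), "3x3")
})

test_that("preprocessing pipeline composes its three stages", {
  # identity contrast branch + constant-preserving guided filter + kernel sum
  const <- matrix(150, 16, 16)
  out <- preprocessImage(const)
  expect_equal(matrix(out, 16, 16), matrix(150 * 6 / 17, 16, 16),
               tolerance = 1e-10)
  ims <- attr(out, "intermediates")
  expect_named(ims, c("contrast", "detail", "highpass"))
  expect_length(ims, 3)
  # detail gain 1 makes steps 1-2 the identity on the identity branch
  img <- randomImage(16, seed = 8, lo = 120, hi = 180)
  stopifnot(mean(img) >= 100, mean(img) < 180)
  out1 <- preprocessImage(img, guidedParams = GuidedFilterParams(detailGain = 1))
  expect_equal(matrix(out1, 16, 16), highpassFilter(img), tolerance = 1e-10)
})
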