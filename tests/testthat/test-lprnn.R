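# The recurrent-convolutional residual denoiser: construction, losses,
# augmentation, training behaviour, full-image inference and serialization.

test_that("a freshly built model is the identity and is seeded", {
  m1 <- buildDenoiser(DenoiserConfig(seed = 3))
  m2 <- buildDenoiser(DenoiserConfig(seed = 3))
  expect_identical(modelWeights(m1), modelWeights(m2))
  m3 <- buildDenoiser(DenoiserConfig(seed = 4))
  expect_false(identical(modelWeights(m1), modelWeights(m3)))
  # zero-initialized output layer => zero predicted noise => identity
  img <- tinyPhantom(1, 40)
  out <- denoise(buildDenoiser(DenoiserConfig(patchSize = 16)), img)
  expect_equal(out, img, tolerance = 1e-12)
})

test_that("the default architecture is compact", {
  m <- buildDenoiser(DenoiserConfig())
  # 5*5*8 + 8 feature weights, 5*5*8*8 + 8 recurrent, 8 + 1 mixing
  expect_identical(nParameters(m), 1825L)
  expect_lt(nParameters(m), 100000L)
  expect_error(DenoiserConfig(patchSize = 33), "divisible")
  expect_error(DenoiserConfig(convKernel = 4), "odd")
})

test_that("edge loss measures vertical-gradient mismatch", {
  a <- randomImage(8, seed = 1)
  expect_equal(edgeLoss(a, a), 0)
  expect_equal(edgeLoss(a + 12.5, a), 0)  # offset-invariant
  target <- matrix(rep(c(0, 10), 4), 8, 8)  # rows alternate 0,10
  pred <- matrix(0, 8, 8)
  expect_equal(edgeLoss(pred, target), 10)
  expect_error(edgeLoss(a, randomImage(6)), "shape")
})

test_that("edge loss is a pseudometric modulo additive constants", {
  x <- randomImage(10, seed = 2)
  y <- randomImage(10, seed = 3)
  z <- randomImage(10, seed = 4)
  expect_equal(edgeLoss(x, y), edgeLoss(y, x))
  expect_lte(edgeLoss(x, z), edgeLoss(x, y) + edgeLoss(y, z) + 1e-12)
  expect_gte(edgeLoss(x, y), 0)
})

test_that("composite loss combines its terms linearly", {
  a <- randomImage(8, seed = 5)
  expect_equal(compositeLoss(a, a, LossWeights(1, 0.1, 0)), 0)
  expect_equal(compositeLoss(a + 5, a, LossWeights(1, 0, 0)), 5)
  target <- matrix(rep(c(0, 10), 4), 8, 8)
  pred <- matrix(0, 8, 8)
  expect_equal(compositeLoss(pred, target, LossWeights(0, 2, 0)), 2 * 10)
  # linear in each weight
  w1 <- compositeLoss(pred, target, LossWeights(1, 1, 0))
  expect_equal(compositeLoss(pred, target, LossWeights(3, 1, 0)) -
                 compositeLoss(pred, target, LossWeights(2, 1, 0)),
               w1 - compositeLoss(pred, target, LossWeights(0, 1, 0)))
  # adversarial term requires a critic score
  expect_error(compositeLoss(pred, target, LossWeights(1, 0, 0.5)),
               "criticScore")
  expect_equal(compositeLoss(a, a, LossWeights(1, 0, 2), criticScore = 0), 1)
})

test_that("augmentation yields the dihedral orbit, applied pairwise", {
  clean <- tinyPhantom(2, 24)
  noisy <- addSpeckle(clean, NoiseSpec("speckle", looks = 4, seed = 1))
  aug <- augmentPairs(list(list(clean = clean, noisy = noisy)))
  expect_length(aug, 8)
  # each output clean image is one of the 8 transforms of the input, and the
  # noisy member underwent the same transform
  tfs <- list(function(m) m,
              despeckle:::rot90cw,
              function(m) despeckle:::rot90cw(despeckle:::rot90cw(m)),
              function(m) despeckle:::rot90cw(despeckle:::rot90cw(despeckle:::rot90cw(m))),
              function(m) m[, ncol(m):1],
              function(m) m[nrow(m):1, ],
              function(m) t(m),
              function(m) despeckle:::rot90cw(despeckle:::rot90cw(t(m))))
  for (pr in aug) {
    match <- which(vapply(tfs, function(tf) identical(tf(clean), pr$clean),
                          logical(1)))
    expect_length(match, 1)
    expect_identical(tfs[[match]](noisy), pr$noisy)
  }
  # a symmetric constant image is fixed by the whole orbit
  cst <- matrix(7, 16, 16)
  augC <- augmentPairs(list(list(clean = cst, noisy = cst)))
  expect_true(all(vapply(augC, function(p) identical(p$clean, cst),
                         logical(1))))
})

test_that("training respects the learning rate and logs every iteration", {
  ds <- makeDataset(4, 1, PhantomSpec(16, 16, nLesions = 1, textureScale = 3),
                    NoiseSpec("speckle", looks = 4), seed = 5)
  model <- buildDenoiser(DenoiserConfig(patchSize = 16, seed = 1))
  frozen <- trainDenoiser(model, ds$train, LossWeights(),
                          TrainConfig(iterations = 3, learningRate = 0,
                                      augment = FALSE, seed = 1))
  expect_identical(modelWeights(frozen$model), modelWeights(model))
  fit <- trainDenoiser(model, ds$train, LossWeights(),
                       TrainConfig(iterations = 25, augment = TRUE, seed = 1))
  expect_identical(nrow(fit$history), 25L)
  expect_true(all(fit$history$mse >= 0))
  expect_lt(fit$history$totalLoss[25], fit$history$totalLoss[1])
  # training is reproducible under a fixed seed
  fit2 <- trainDenoiser(model, ds$train, LossWeights(),
                        TrainConfig(iterations = 25, augment = TRUE,
                                    seed = 1))
  expect_equal(modelWeights(fit$model), modelWeights(fit2$model))
})

test_that("adversarial training runs and stays finite when enabled", {
  ds <- makeDataset(2, 1, PhantomSpec(16, 16, nLesions = 1, textureScale = 3),
                    NoiseSpec("speckle", looks = 4), seed = 6)
  model <- buildDenoiser(DenoiserConfig(patchSize = 16, seed = 2))
  fit <- trainDenoiser(model, ds$train, LossWeights(1, 0.1, 0.01),
                       TrainConfig(iterations = 5, augment = FALSE,
                                   seed = 2))
  expect_true(all(is.finite(fit$history$totalLoss)))
})

test_that("denoise preserves shape and rejects undersized images", {
  model <- buildDenoiser(DenoiserConfig(patchSize = 16))
  img <- tinyPhantom(3, 40)
  out <- denoise(model, img)
  expect_identical(dim(out), dim(img))
  expect_error(denoise(model, matrix(1, 8, 8)), "pad")
  # overlap blending normalizes to one: identity model on a constant image
  cst <- matrix(33, 40, 40)
  expect_equal(denoise(model, cst), cst, tolerance = 1e-12)
})

test_that("models round-trip through the flat-array archive", {
  ds <- makeDataset(2, 1, PhantomSpec(16, 16, nLesions = 1, textureScale = 3),
                    NoiseSpec("speckle", looks = 4), seed = 8)
  fit <- trainDenoiser(buildDenoiser(DenoiserConfig(patchSize = 16,
                                                    seed = 3)),
                       ds$train, LossWeights(),
                       TrainConfig(iterations = 5, augment = FALSE, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  writeDenoiser(fit$model, path)
  back <- readDenoiser(path)
  expect_equal(modelWeights(back), modelWeights(fit$model))
  img <- tinyPhantom(4, 32)
  expect_equal(denoise(back, img), denoise(fit$model, img))
})
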