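# Shared fixtures. Everything is generated in code; heavyweight artifacts
# (the two trained ablation models) are built once per test run and cached.

tinyPhantom <- function(seed = 1, n = 48) {
  generatePhantom(PhantomSpec(n, n, nLesions = 2, textureScale = 6,
                              seed = seed))
}

randomImage <- function(n = 16, seed = 1, lo = 0, hi = 255) {
  withr::with_seed(seed, matrix(stats::runif(n * n, lo, hi), n, n))
}

# total variation (anisotropic): sum of absolute horizontal + vertical
# first differences
totalVariation <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  sum(abs(img[-1, ] - img[-h, ])) + sum(abs(img[, -1] - img[, -w]))
}

# Study conditions for the end-to-end and ablation checks: 64x64 two-lesion
# speckle phantoms at 4 looks, 12 training and 20 held-out test images,
# 300 training iterations. Trained once, shared by the acceptance tests.
.ablationCache <- new.env(parent = emptyenv())

ablationFixture <- function() {
  if (!is.null(.ablationCache$fit)) return(.ablationCache$fit)
  ds <- makeDataset(12, 20, PhantomSpec(64, 64, nLesions = 2,
                                        textureScale = 6),
                    NoiseSpec("speckle", looks = 4), seed = 11)
  tc <- TrainConfig(iterations = 300L, batchSize = 16L, seed = 0L)
  fitEdge <- trainDenoiser(buildDenoiser(DenoiserConfig(seed = 0L)),
                           ds$train, LossWeights(1, 0.1, 0), tc)
  fitPlain <- trainDenoiser(buildDenoiser(DenoiserConfig(seed = 0L)),
                            ds$train, LossWeights(1, 0, 0), tc)
  evalSuite <- function(model) {
    t(vapply(ds$test, function(p) {
      d <- denoise(model, p$noisy)
      c(psnrNoisy = psnr(p$clean, p$noisy),
        psnrDenoised = psnr(p$clean, d),
        epi = epi(p$clean, d))
    }, numeric(3)))
  }
  .ablationCache$fit <- list(dataset = ds,
                             edge = fitEdge, plain = fitPlain,
                             edgeEval = evalSuite(fitEdge$model),
                             plainEval = evalSuite(fitPlain$model))
  .ablationCache$fit
}
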