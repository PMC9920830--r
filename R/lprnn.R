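# Public interface of the recurrent-convolutional residual denoiser: model
# construction, the edge-sensitive composite loss, training-pair
# augmentation, the training loop, full-image denoising by overlapping patch
# tiling, and model (de)serialization.

#' Build a denoiser model
#'
#' Constructs the patch-residual denoiser: a feature-extraction convolution
#' (`featureChannels` maps, `convKernel` kernel), a max-pool/upsample
#' "logical pool" branch injected into every refinement step,
#' `recurrentSteps` weight-shared convolutional refinement iterations, and a
#' 1x1 mixing layer predicting the noise field; the output is the input patch
#' minus the predicted noise. Hidden weights are seeded He-normal draws; the
#' output layer is zero-initialized, so a freshly built model is exactly the
#' identity map.
#'
#' @param config a [DenoiserConfig-class].
#' @return a [DespeckleModel-class].
#' @examples
#' model <- buildDenoiser(DenoiserConfig())
#' nParameters(model)
#' @export
buildDenoiser <- function(config = DenoiserConfig()) {
  stopifnot(is(config, "DenoiserConfig"))
  validObject(config)
  k2 <- config@convKernel^2
  C <- config@featureChannels
  wts <- withr::with_seed(config@seed, {
    list(W1 = matrix(stats::rnorm(k2 * C, sd = sqrt(2 / k2)), k2, C),
         b1 = numeric(C),
         Wr = matrix(stats::rnorm(k2 * C * C, sd = sqrt(2 / (k2 * C))),
                     k2 * C, C),
         br = numeric(C),
         wOut = matrix(0, C, 1L),
         bOut = 0)
  })
  new("DespeckleModel", config = config, weights = wts,
      nParameters = as.integer(sum(vapply(wts, length, integer(1)))))
}

#' Edge-information loss
#'
#' Mean absolute difference between the vertical first finite differences of
#' two images: `mean(|Dv(pred) - Dv(target)|)` with
#' `Dv(x)[i, j] = x[i+1, j] - x[i, j]`. Vertical gradients carry the
#' anatomically dominant edge structure in breast ultrasound, so this term
#' penalizes edge smearing directly. Invariant to adding a constant to either
#' image; a pseudometric (zero between images that differ by a constant).
#'
#' @param pred,target numeric matrices of identical shape, at least 2 rows.
#' @return non-negative scalar loss.
#' @examples
#' a <- matrix(0, 4, 4)
#' edgeLoss(a, a)  # 0
#' @export
edgeLoss <- function(pred, target) {
  assertImage(pred, minDim = 2L)
  assertImage(target, minDim = 2L)
  assertSameShape(pred, target)
  h <- nrow(pred)
  dv <- (pred[2:h, , drop = FALSE] - pred[1:(h - 1), , drop = FALSE]) -
    (target[2:h, , drop = FALSE] - target[1:(h - 1), , drop = FALSE])
  mean(abs(dv))
}

#' Composite training objective
#'
#' `advWeight * 0.5 * (criticScore - 1)^2 + l1Weight * mean(|pred - target|)
#' + edgeWeight * edgeLoss(pred, target)`. The adversarial term is the
#' least-squares generator objective against a patch critic and is only
#' evaluated when `advWeight > 0`, in which case `criticScore` must be
#' supplied.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param weights a [LossWeights-class].
#' @param criticScore scalar critic output for `pred`; required iff
#'   `advWeight > 0`.
#' @return scalar loss.
#' @export
compositeLoss <- function(pred, target, weights = LossWeights(),
                          criticScore = NULL) {
  assertImage(pred)
  assertImage(target)
  assertSameShape(pred, target)
  stopifnot(is(weights, "LossWeights"))
  loss <- weights@l1Weight * mean(abs(pred - target)) +
    weights@edgeWeight * edgeLoss(pred, target)
  if (weights@advWeight > 0) {
    if (is.null(criticScore)) {
      stop("criticScore must be supplied when advWeight > 0", call. = FALSE)
    }
    loss <- loss + weights@advWeight * 0.5 * (criticScore - 1)^2
  }
  loss
}

rot90cw <- function(m) t(m[nrow(m):1L, , drop = FALSE])

#' Expand training pairs by the eight dihedral symmetries
#'
#' Applies the identity, the three 90-degree rotations, the horizontal and
#' vertical flips and the two diagonal reflections to every (clean, noisy)
#' pair, with the same transform applied to both members, yielding eight
#' times as many pairs. Deterministic; `seed` is accepted for interface
#' symmetry with the other generators but unused.
#'
#' @param pairs list of `list(clean = matrix, noisy = matrix)`.
#' @param seed ignored (the expansion is deterministic).
#' @return list of length `8 * length(pairs)`.
#' @export
augmentPairs <- function(pairs, seed = NULL) {
  if (length(pairs) == 0L) stop("no training pairs supplied", call. = FALSE)
  transforms <- list(
    function(m) m,
    rot90cw,
    function(m) rot90cw(rot90cw(m)),
    function(m) rot90cw(rot90cw(rot90cw(m))),
    function(m) m[, ncol(m):1L, drop = FALSE],
    function(m) m[nrow(m):1L, , drop = FALSE],
    function(m) t(m),
    function(m) rot90cw(rot90cw(t(m)))
  )
  out <- vector("list", 8L * length(pairs))
  i <- 0L
  for (pr in pairs) {
    for (tf in transforms) {
      i <- i + 1L
      out[[i]] <- list(clean = tf(pr$clean), noisy = tf(pr$noisy))
    }
  }
  out
}

# Deterministic monitoring patches: centre crops of up to maxN evenly spaced
# pairs, as (hw x n) matrices on the [0, 1] scale.
monitorPatches <- function(pairs, ps, maxN = 32L) {
  idx <- unique(round(seq(1L, length(pairs),
                          length.out = min(maxN, length(pairs)))))
  crop <- function(m) {
    r0 <- (nrow(m) - ps) %/% 2L
    c0 <- (ncol(m) - ps) %/% 2L
    as.vector(m[r0 + seq_len(ps), c0 + seq_len(ps)]) / 255
  }
  list(noisy = vapply(pairs[idx], function(p) crop(p$noisy), numeric(ps * ps)),
       clean = vapply(pairs[idx], function(p) crop(p$clean), numeric(ps * ps)))
}

#' Train the denoiser
#'
#' Minimizes the composite objective (L1 fidelity + edge loss, optionally an
#' adversarial term) with Adam over patches sampled from the training pairs.
#' When `trainConfig@augment` is set, pairs are first expanded by the eight
#' dihedral symmetries. Training is reproducible under a fixed seed up to
#' floating-point nondeterminism of the BLAS. A non-finite loss aborts with a
#' diagnostic.
#'
#' Every iteration, the mean squared error (in squared gray levels), the
#' false-recognition rate (5 gray-level tolerance) and the composite loss are
#' logged on a fixed monitoring subset of up to 32 training patches.
#'
#' @param model a [DespeckleModel-class] (typically fresh from
#'   [buildDenoiser()]).
#' @param pairs list of `list(clean, noisy)` matrices, each at least
#'   `patchSize` in both dimensions.
#' @param lossWeights a [LossWeights-class].
#' @param trainConfig a [TrainConfig-class].
#' @return `list(model = trained model, history = data.frame(iteration, mse,
#'   falseRecognitionRate, totalLoss))` with one history row per iteration.
#' @export
trainDenoiser <- function(model, pairs, lossWeights = LossWeights(),
                          trainConfig = TrainConfig()) {
  stopifnot(is(model, "DespeckleModel"), is(lossWeights, "LossWeights"),
            is(trainConfig, "TrainConfig"))
  validObject(lossWeights)
  validObject(trainConfig)
  if (length(pairs) == 0L) stop("no training pairs supplied", call. = FALSE)
  cfg <- model@config
  ps <- cfg@patchSize
  for (pr in pairs) {
    if (nrow(pr$clean) < ps || ncol(pr$clean) < ps) {
      stop(sprintf("training images must be at least %dx%d", ps, ps),
           call. = FALSE)
    }
    assertSameShape(pr$clean, pr$noisy)
  }
  if (trainConfig@augment) pairs <- augmentPairs(pairs)
  geo <- denoiserGeometry(cfg)
  wts <- model@weights
  state <- adamInit(wts)
  useCritic <- lossWeights@advWeight > 0
  if (useCritic) {
    cw <- criticInit(geo$hw, trainConfig@seed + 1L)
    cState <- adamInit(cw)
  }
  mon <- monitorPatches(pairs, ps)
  nMon <- ncol(mon$noisy)
  history <- data.frame(iteration = seq_len(trainConfig@iterations),
                        mse = NA_real_, falseRecognitionRate = NA_real_,
                        totalLoss = NA_real_)
  withr::with_seed(trainConfig@seed, {
    for (it in seq_len(trainConfig@iterations)) {
      grads <- zeroGrads(wts)
      if (useCritic) cGrads <- zeroGrads(cw)
      batchLoss <- 0
      B <- trainConfig@batchSize
      pick <- sample.int(length(pairs), B, replace = TRUE)
      for (b in seq_len(B)) {
        pr <- pairs[[pick[b]]]
        r0 <- sample.int(nrow(pr$clean) - ps + 1L, 1L) - 1L
        c0 <- sample.int(ncol(pr$clean) - ps + 1L, 1L) - 1L
        x <- as.vector(pr$noisy[r0 + seq_len(ps), c0 + seq_len(ps)]) / 255
        y <- as.vector(pr$clean[r0 + seq_len(ps), c0 + seq_len(ps)]) / 255
        fw <- lprnnForward(wts, geo, x, keepCache = TRUE)
        lg <- patchLossGrad(fw$out, y, ps, lossWeights)
        loss <- lg$loss
        dOut <- lg$grad
        if (useCritic) {
          cf <- criticForward(cw, fw$out)
          loss <- loss + lossWeights@advWeight * 0.5 * (cf$score - 1)^2
          gb <- criticBackward(cw, cf,
                               lossWeights@advWeight * (cf$score - 1))
          dOut <- dOut + gb$dx
          # critic update targets: clean -> 1, denoised -> 0 (LSGAN)
          cfReal <- criticForward(cw, y)
          gReal <- criticBackward(cw, cfReal, cfReal$score - 1)
          cfFake <- criticForward(cw, fw$out)
          gFake <- criticBackward(cw, cfFake, cfFake$score)
          for (nm in names(cw)) {
            cGrads[[nm]] <- cGrads[[nm]] +
              (gReal$grads[[nm]] + gFake$grads[[nm]]) / B
          }
        }
        batchLoss <- batchLoss + loss / B
        grads <- lprnnBackward(wts, geo, fw, dOut / B, grads)
      }
      if (!is.finite(batchLoss)) {
        stop(sprintf("training diverged at iteration %d (loss = %g); lower the learning rate",
                     it, batchLoss), call. = FALSE)
      }
      if (trainConfig@learningRate > 0) {
        upd <- adamStep(wts, grads, state, trainConfig@learningRate)
        wts <- upd$wts
        state <- upd$state
        if (useCritic) {
          updC <- adamStep(cw, cGrads, cState, trainConfig@learningRate)
          cw <- updC$wts
          cState <- updC$state
        }
      }
      # monitoring pass on the fixed patch subset
      se <- 0
      nBad <- 0
      monLoss <- 0
      for (j in seq_len(nMon)) {
        o <- lprnnForward(wts, geo, mon$noisy[, j])$out
        d <- o - mon$clean[, j]
        se <- se + mean(d^2)
        nBad <- nBad + mean(abs(d) > 5 / 255)
        monLoss <- monLoss +
          patchLossGrad(o, mon$clean[, j], ps, lossWeights)$loss
      }
      history$mse[it] <- se / nMon * 255^2
      history$falseRecognitionRate[it] <- nBad / nMon
      history$totalLoss[it] <- monLoss / nMon
    }
  })
  model@weights <- wts
  list(model = model, history = history)
}

#' Denoise a full image
#'
#' Tiles the image into overlapping `patchSize` patches (stride
#' `patchSize / 2`, last tile flush with the border), denoises each patch and
#' blends overlaps by averaging. The output has the input's shape; a model
#' with a zero output layer (e.g. fresh from [buildDenoiser()]) returns the
#' input exactly.
#'
#' @param model a [DespeckleModel-class].
#' @param img numeric matrix at least `patchSize` in both dimensions; pad
#'   smaller images before calling.
#' @return denoised image, same shape, in gray levels.
#' @examples
#' model <- buildDenoiser(DenoiserConfig(patchSize = 16))
#' img <- generatePhantom(PhantomSpec(32, 32, seed = 1))
#' out <- denoise(model, img)
#' all.equal(out, img)  # identity at initialization
#' @export
denoise <- function(model, img) {
  stopifnot(is(model, "DespeckleModel"))
  assertImage(img)
  cfg <- model@config
  ps <- cfg@patchSize
  if (nrow(img) < ps || ncol(img) < ps) {
    stop(sprintf("image (%dx%d) smaller than the %dx%d patch; pad it first",
                 nrow(img), ncol(img), ps, ps), call. = FALSE)
  }
  geo <- denoiserGeometry(cfg)
  wts <- model@weights
  stride <- max(ps %/% 2L, 1L)
  starts <- function(n) unique(c(seq(1L, n - ps + 1L, by = stride),
                                 n - ps + 1L))
  acc <- matrix(0, nrow(img), ncol(img))
  wt <- matrix(0, nrow(img), ncol(img))
  for (r0 in starts(nrow(img))) {
    for (c0 in starts(ncol(img))) {
      ri <- r0 - 1L + seq_len(ps)
      ci <- c0 - 1L + seq_len(ps)
      x <- as.vector(img[ri, ci]) / 255
      o <- lprnnForward(wts, geo, x)$out
      acc[ri, ci] <- acc[ri, ci] + matrix(o, ps, ps)
      wt[ri, ci] <- wt[ri, ci] + 1
    }
  }
  acc / wt * 255
}

#' Save / load a denoiser model
#'
#' The model is serialized as a flat-array archive: a single JSON file whose
#' header carries the architecture and whose body stores every weight array
#' with its dimensions, at full precision. The round trip is lossless.
#'
#' @param model a [DespeckleModel-class].
#' @param path file path (conventionally `.json`).
#' @return `path` invisibly (write); the restored model (read).
#' @export
writeDenoiser <- function(model, path) {
  stopifnot(is(model, "DespeckleModel"))
  cfg <- model@config
  obj <- list(
    format = "despeckle-model-1",
    architecture = list(patchSize = cfg@patchSize,
                        convKernel = cfg@convKernel,
                        poolSize = cfg@poolSize,
                        featureChannels = cfg@featureChannels,
                        recurrentSteps = cfg@recurrentSteps,
                        seed = cfg@seed),
    nParameters = model@nParameters,
    weights = lapply(model@weights, function(w) {
      list(dim = if (is.matrix(w)) dim(w) else length(w),
           values = as.vector(w))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDenoiser
#' @export
readDenoiser <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "despeckle-model-1")) {
    stop("not a despeckle model file: ", path, call. = FALSE)
  }
  a <- obj$architecture
  cfg <- DenoiserConfig(patchSize = a$patchSize, convKernel = a$convKernel,
                        poolSize = a$poolSize,
                        featureChannels = a$featureChannels,
                        recurrentSteps = a$recurrentSteps, seed = a$seed)
  wts <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2L) {
      matrix(w$values, w$dim[1L], w$dim[2L])
    } else if (identical(w$dim, 1L) || length(w$values) == 1L) {
      as.numeric(w$values)
    } else {
      as.numeric(w$values)
    }
  })
  names(wts) <- names(obj$weights)
  wts$bOut <- as.numeric(wts$bOut)
  new("DespeckleModel", config = cfg, weights = wts,
      nParameters = as.integer(obj$nParameters))
}
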