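#' @import methods
NULL

# ---------------------------------------------------------------------------
# S4 parameter / configuration / report classes. Images themselves are plain
# numeric matrices in gray-level units; these classes carry the tunable state
# of each pipeline stage and validate it once, at construction.
# ---------------------------------------------------------------------------

#' Phantom specification
#'
#' Describes a synthetic breast-tissue-like test image: a smooth low-frequency
#' background with a chosen number of soft-edged elliptical lesions, standing
#' in for curated clinical image corpora when validating the despeckling
#' pipeline. All intensities are in 8-bit gray levels.
#'
#' @slot height,width image dimensions in pixels (at least 3).
#' @slot nLesions number of elliptical lesions (may be 0).
#' @slot backgroundLevel mean background intensity, gray levels.
#' @slot lesionContrast lesion-minus-background intensity difference, gray
#'   levels; \code{backgroundLevel + lesionContrast} must stay in [0, 255].
#' @slot textureScale correlation length of the background texture in pixels;
#'   \code{Inf} requests a perfectly flat background.
#' @slot seed integer seed making the phantom reproducible.
#' @seealso [generatePhantom()], [makeDataset()]
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer", nLesions = "integer",
                 backgroundLevel = "numeric", lesionContrast = "numeric",
                 textureScale = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@height < 3L || object@width < 3L)
      msg <- c(msg, "height and width must be >= 3")
    if (object@nLesions < 0L)
      msg <- c(msg, "nLesions must be >= 0")
    if (object@backgroundLevel < 0 || object@backgroundLevel > 255)
      msg <- c(msg, "backgroundLevel must lie in [0, 255]")
    lo <- object@backgroundLevel + min(object@lesionContrast, 0)
    hi <- object@backgroundLevel + max(object@lesionContrast, 0)
    if (lo < 0 || hi > 255)
      msg <- c(msg, "backgroundLevel + lesionContrast must stay within [0, 255]")
    if (!(is.finite(object@textureScale) && object@textureScale > 0) &&
        !is.infinite(object@textureScale))
      msg <- c(msg, "textureScale must be positive (possibly Inf)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PhantomSpec Constructor with study-scale defaults: 128x128
#'   pixels, three lesions of +60 gray levels on a background of 120 with an
#'   8-pixel texture correlation length.
#' @param height,width,nLesions,backgroundLevel,lesionContrast,textureScale,seed
#'   see slot descriptions.
#' @export
PhantomSpec <- function(height = 128L, width = 128L, nLesions = 3L,
                        backgroundLevel = 120, lesionContrast = 60,
                        textureScale = 8, seed = 0L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      nLesions = as.integer(nLesions),
      backgroundLevel = as.numeric(backgroundLevel),
      lesionContrast = as.numeric(lesionContrast),
      textureScale = as.numeric(textureScale), seed = as.integer(seed))
}

#' Noise specification
#'
#' The corruption model applied to clean images: either fully developed
#' multiplicative speckle with a given number of looks, or additive white
#' Gaussian noise at a target signal-to-noise ratio in dB.
#'
#' @slot kind `"speckle"` or `"awgn"`.
#' @slot looks effective number of looks (speckle only); the multiplicative
#'   field has unit mean and variance `1/looks`.
#' @slot snrDb target SNR in decibels (awgn only).
#' @slot seed integer seed.
#' @seealso [addSpeckle()], [addAwgnAtSnr()]
#' @export
setClass("NoiseSpec",
  representation(kind = "character", looks = "numeric", snrDb = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("speckle", "awgn"))
      msg <- c(msg, "kind must be 'speckle' or 'awgn'")
    if (object@kind == "speckle" && !(object@looks > 0))
      msg <- c(msg, "looks must be > 0 for speckle noise")
    if (object@kind == "awgn" && is.na(object@snrDb))
      msg <- c(msg, "snrDb must be given for awgn noise")
    if (length(msg)) msg else TRUE
  })

#' @describeIn NoiseSpec Constructor. Exactly the fields of the chosen kind
#'   are used: `looks` for speckle, `snrDb` for awgn.
#' @param kind,looks,snrDb,seed see slot descriptions.
#' @export
NoiseSpec <- function(kind = c("speckle", "awgn"), looks = NA_real_,
                      snrDb = NA_real_, seed = 0L) {
  kind <- match.arg(kind)
  if (kind == "speckle" && is.na(looks)) looks <- 4
  new("NoiseSpec", kind = kind, looks = as.numeric(looks),
      snrDb = as.numeric(snrDb), seed = as.integer(seed))
}

#' Piecewise contrast-enhancement parameters
#'
#' Coefficients of the logarithmic and exponential gray-level transforms and
#' the grayscale-mean thresholds that select between them. With the default
#' endpoint-normalized coefficients both transforms map [0, 255] onto
#' [0, 255] and are exact inverses of one another.
#'
#' @slot aLog,bLog,cLog log-branch scale, exponent and offset; `bLog` must lie
#'   in (0, 1].
#' @slot aExp,bExp,cExp exp-branch scale, base and offset; `bExp` must exceed 1.
#' @slot tLow,tHigh,tMax grayscale-mean thresholds (defaults 100, 180, 260):
#'   means in [0, tLow) take the log branch, [tLow, tHigh) the identity,
#'   [tHigh, tMax) the exp branch; means at or above tMax are rejected.
#' @seealso [piecewiseContrast()]
#' @export
setClass("ContrastParams",
  representation(aLog = "numeric", bLog = "numeric", cLog = "numeric",
                 aExp = "numeric", bExp = "numeric", cExp = "numeric",
                 tLow = "numeric", tHigh = "numeric", tMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@bLog > 0 && object@bLog <= 1))
      msg <- c(msg, "bLog must lie in (0, 1]")
    if (!(object@bExp > 1))
      msg <- c(msg, "bExp must be > 1")
    if (!(0 < object@tLow && object@tLow < object@tHigh &&
          object@tHigh < object@tMax))
      msg <- c(msg, "thresholds must satisfy 0 < tLow < tHigh < tMax")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ContrastParams Constructor. Defaults normalize both transform
#'   branches so that 0 maps to 0 and 255 maps to 255.
#' @param aLog,bLog,cLog,aExp,bExp,cExp,tLow,tHigh,tMax see slot descriptions.
#' @export
ContrastParams <- function(aLog = 255 / log(256), bLog = 1, cLog = 0,
                           aExp = NULL, bExp = 256, cExp = 0,
                           tLow = 100, tHigh = 180, tMax = 260) {
  if (is.null(aExp)) aExp <- 255 / (bExp - 1)
  new("ContrastParams", aLog = as.numeric(aLog), bLog = as.numeric(bLog),
      cLog = as.numeric(cLog), aExp = as.numeric(aExp),
      bExp = as.numeric(bExp), cExp = as.numeric(cExp),
      tLow = as.numeric(tLow), tHigh = as.numeric(tHigh),
      tMax = as.numeric(tMax))
}

#' Guided-filter parameters
#'
#' Controls the edge-preserving smoothing and detail-boost stage. The filter
#' operates internally on intensities rescaled to [0, 1], so `epsilon` is
#' expressed on that scale.
#'
#' @slot radius half-width of the square filter window; the window holds
#'   `(2*radius + 1)^2` pixels and must fit inside the image.
#' @slot epsilon smoothing regularizer (> 0), on [0, 1]-rescaled intensities.
#' @slot detailGain detail-layer gain F applied as
#'   `base + F * (original - base)`; `F = 1` reproduces the original image.
#' @seealso [guidedFilter()], [detailEnhance()]
#' @export
setClass("GuidedFilterParams",
  representation(radius = "integer", epsilon = "numeric",
                 detailGain = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@radius < 1L) msg <- c(msg, "radius must be >= 1")
    if (!(object@epsilon > 0)) msg <- c(msg, "epsilon must be > 0")
    if (object@detailGain < 0) msg <- c(msg, "detailGain must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn GuidedFilterParams Constructor (defaults: radius 2,
#'   epsilon 0.01, detailGain 2).
#' @param radius,epsilon,detailGain see slot descriptions.
#' @export
GuidedFilterParams <- function(radius = 2L, epsilon = 0.01, detailGain = 2) {
  new("GuidedFilterParams", radius = as.integer(radius),
      epsilon = as.numeric(epsilon), detailGain = as.numeric(detailGain))
}

#' Denoiser architecture configuration
#'
#' Shape of the recurrent-convolutional residual denoiser: a feature-
#' extraction convolution, a max-pool/upsample "logical pool" branch, a
#' weight-shared recurrent refinement stack and a 1x1 mixing layer whose
#' output is subtracted from the input patch (residual form).
#'
#' @slot patchSize side length of square training/inference patches; must be
#'   divisible by `poolSize`.
#' @slot convKernel odd side length of the convolution kernels.
#' @slot poolSize max-pooling window/stride.
#' @slot featureChannels number of feature maps.
#' @slot recurrentSteps number of weight-shared refinement iterations (>= 1).
#' @slot seed integer seed for weight initialization.
#' @seealso [buildDenoiser()]
#' @export
setClass("DenoiserConfig",
  representation(patchSize = "integer", convKernel = "integer",
                 poolSize = "integer", featureChannels = "integer",
                 recurrentSteps = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@patchSize < 4L) msg <- c(msg, "patchSize must be >= 4")
    if (object@patchSize %% object@poolSize != 0L)
      msg <- c(msg, "patchSize must be divisible by poolSize")
    if (object@convKernel %% 2L == 0L || object@convKernel < 1L)
      msg <- c(msg, "convKernel must be odd and positive")
    if (object@featureChannels < 1L)
      msg <- c(msg, "featureChannels must be >= 1")
    if (object@recurrentSteps < 1L)
      msg <- c(msg, "recurrentSteps must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' @describeIn DenoiserConfig Constructor with the published layer sizes:
#'   8 feature maps over 32x32 patches, 5x5 kernels, 2x2 pooling, three
#'   recurrent steps.
#' @param patchSize,convKernel,poolSize,featureChannels,recurrentSteps,seed
#'   see slot descriptions.
#' @export
DenoiserConfig <- function(patchSize = 32L, convKernel = 5L, poolSize = 2L,
                           featureChannels = 8L, recurrentSteps = 3L,
                           seed = 0L) {
  new("DenoiserConfig", patchSize = as.integer(patchSize),
      convKernel = as.integer(convKernel), poolSize = as.integer(poolSize),
      featureChannels = as.integer(featureChannels),
      recurrentSteps = as.integer(recurrentSteps), seed = as.integer(seed))
}

#' Loss weights for denoiser training
#'
#' Weights of the composite objective: an optional adversarial (critic) term,
#' an L1 fidelity term and the vertical-gradient edge-preservation term.
#'
#' @slot l1Weight weight of the mean-absolute-error term.
#' @slot edgeWeight weight of the edge loss (vertical finite differences).
#' @slot advWeight weight of the adversarial term; 0 (the default) disables
#'   the critic entirely.
#' @seealso [compositeLoss()], [trainDenoiser()]
#' @export
setClass("LossWeights",
  representation(l1Weight = "numeric", edgeWeight = "numeric",
                 advWeight = "numeric"),
  validity = function(object) {
    w <- c(object@l1Weight, object@edgeWeight, object@advWeight)
    if (any(w < 0)) return("loss weights must be >= 0")
    if (sum(w) <= 0) return("at least one loss weight must be > 0")
    TRUE
  })

#' @describeIn LossWeights Constructor (defaults: l1Weight 1, edgeWeight 0.1,
#'   advWeight 0).
#' @param l1Weight,edgeWeight,advWeight see slot descriptions.
#' @export
LossWeights <- function(l1Weight = 1, edgeWeight = 0.1, advWeight = 0) {
  new("LossWeights", l1Weight = as.numeric(l1Weight),
      edgeWeight = as.numeric(edgeWeight), advWeight = as.numeric(advWeight))
}

#' Training configuration
#'
#' @slot iterations number of optimization iterations.
#' @slot batchSize patches per iteration.
#' @slot learningRate Adam step size.
#' @slot augment whether to expand the training pairs by the eight dihedral
#'   flips/rotations before training.
#' @slot seed integer seed governing patch sampling.
#' @seealso [trainDenoiser()]
#' @export
setClass("TrainConfig",
  representation(iterations = "integer", batchSize = "integer",
                 learningRate = "numeric", augment = "logical",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn TrainConfig Constructor (defaults: 100 iterations, batch 16,
#'   learning rate 1e-3, augmentation on).
#' @param iterations,batchSize,learningRate,augment,seed see slot
#'   descriptions.
#' @export
TrainConfig <- function(iterations = 100L, batchSize = 16L,
                        learningRate = 1e-3, augment = TRUE, seed = 0L) {
  new("TrainConfig", iterations = as.integer(iterations),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), augment = isTRUE(augment),
      seed = as.integer(seed))
}

#' Evaluation report
#'
#' Quantitative summary of one denoising result against its clean reference.
#'
#' @slot mse mean squared error, squared gray levels.
#' @slot snrDb signal-to-noise ratio in dB (reference power over error power).
#' @slot psnrDb peak SNR in dB; `Inf` when the images are identical.
#' @slot epi edge preservation index in [-1, 1] (Laplacian-deviation
#'   correlation; 1 means edges perfectly retained).
#' @slot falseRecognitionRate fraction of pixels deviating by more than the
#'   tolerance from the reference.
#' @slot tDes total destruction (processing) time in seconds, summed over
#'   pipeline stages.
#' @seealso [evaluateDenoising()]
#' @export
setClass("EvalReport",
  representation(mse = "numeric", snrDb = "numeric", psnrDb = "numeric",
                 epi = "numeric", falseRecognitionRate = "numeric",
                 tDes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@mse < 0) msg <- c(msg, "mse must be >= 0")
    if (!is.na(object@epi) && (object@epi < -1 - 1e-9 || object@epi > 1 + 1e-9))
      msg <- c(msg, "epi must lie in [-1, 1]")
    if (object@falseRecognitionRate < 0 || object@falseRecognitionRate > 1)
      msg <- c(msg, "falseRecognitionRate must lie in [0, 1]")
    if (object@tDes < 0) msg <- c(msg, "tDes must be >= 0")
    if ((object@mse == 0) != is.infinite(object@psnrDb))
      msg <- c(msg, "psnrDb must be infinite exactly when mse is 0")
    if (length(msg)) msg else TRUE
  })

#' Denoiser model
#'
#' A trained (or freshly initialized) recurrent-convolutional residual
#' denoiser: its architecture plus flat weight arrays. Weight layout:
#' `W1`/`b1` feature-extraction convolution, `Wr`/`br` the weight-shared
#' recurrent convolution, `wOut`/`bOut` the 1x1 mixing layer that predicts the
#' noise field. The output layer is zero-initialized, so an untrained model is
#' exactly the identity.
#'
#' @slot config a [DenoiserConfig-class].
#' @slot weights named list of numeric matrices/vectors.
#' @slot nParameters total trainable parameter count.
#' @seealso [buildDenoiser()], [denoise()], [trainDenoiser()]
#' @export
setClass("DespeckleModel",
  representation(config = "DenoiserConfig", weights = "list",
                 nParameters = "integer"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %dx%d, %d lesion(s), background %.1f, contrast %+.1f, texture %s px, seed %d\n",
              object@height, object@width, object@nLesions,
              object@backgroundLevel, object@lesionContrast,
              format(object@textureScale), object@seed))
})

setMethod("show", "NoiseSpec", function(object) {
  if (object@kind == "speckle") {
    cat(sprintf("NoiseSpec: multiplicative speckle, looks = %g, seed %d\n",
                object@looks, object@seed))
  } else {
    cat(sprintf("NoiseSpec: additive white Gaussian, target SNR = %g dB, seed %d\n",
                object@snrDb, object@seed))
  }
})

setMethod("show", "ContrastParams", function(object) {
  cat(sprintf("ContrastParams: log(a=%.4g, b=%.3g, c=%.3g), exp(a=%.4g, b=%.4g, c=%.3g), thresholds %g/%g/%g\n",
              object@aLog, object@bLog, object@cLog, object@aExp, object@bExp,
              object@cExp, object@tLow, object@tHigh, object@tMax))
})

setMethod("show", "GuidedFilterParams", function(object) {
  cat(sprintf("GuidedFilterParams: radius %d (%dx%d window), epsilon %.4g, detail gain %.3g\n",
              object@radius, 2L * object@radius + 1L, 2L * object@radius + 1L,
              object@epsilon, object@detailGain))
})

setMethod("show", "DenoiserConfig", function(object) {
  cat(sprintf("DenoiserConfig: patch %dx%d, conv %dx%d, pool %dx%d, %d channels, %d recurrent step(s), seed %d\n",
              object@patchSize, object@patchSize, object@convKernel,
              object@convKernel, object@poolSize, object@poolSize,
              object@featureChannels, object@recurrentSteps, object@seed))
})

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights: L1 %.3g, edge %.3g, adversarial %.3g\n",
              object@l1Weight, object@edgeWeight, object@advWeight))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: %d iteration(s), batch %d, lr %.3g, augment %s, seed %d\n",
              object@iterations, object@batchSize, object@learningRate,
              object@augment, object@seed))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport:\n")
  cat(sprintf("  MSE  : %.4f gray^2\n", object@mse))
  cat(sprintf("  SNR  : %.2f dB\n", object@snrDb))
  cat(sprintf("  PSNR : %.2f dB\n", object@psnrDb))
  cat(sprintf("  EPI  : %.4f\n", object@epi))
  cat(sprintf("  FRR  : %.4f\n", object@falseRecognitionRate))
  cat(sprintf("  time : %.3f s\n", object@tDes))
})

setMethod("show", "DespeckleModel", function(object) {
  cat("DespeckleModel (recurrent-convolutional residual denoiser)\n")
  show(object@config)
  cat(sprintf("  %d trainable parameters\n", object@nParameters))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' Accessors for despeckle S4 objects
#'
#' Small read-only accessors; user code should use these instead of reaching
#' into slots.
#'
#' @param object an S4 object from this package.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
denoiserConfig <- function(object) {
  stopifnot(is(object, "DespeckleModel"))
  object@config
}

#' @rdname accessors
#' @export
modelWeights <- function(object) {
  stopifnot(is(object, "DespeckleModel"))
  object@weights
}

#' @rdname accessors
#' @export
nParameters <- function(object) {
  stopifnot(is(object, "DespeckleModel"))
  object@nParameters
}

#' @rdname accessors
#' @export
reportAsList <- function(object) {
  stopifnot(is(object, "EvalReport"))
  list(mse = object@mse, snrDb = object@snrDb, psnrDb = object@psnrDb,
       epi = object@epi, falseRecognitionRate = object@falseRecognitionRate,
       tDes = object@tDes)
}
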