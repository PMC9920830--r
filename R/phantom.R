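# Synthetic phantom generation and noise models. The phantom emulates the
# role of a clinical image corpus: smooth tissue-like background plus
# soft-edged elliptical lesions, so that edge-preservation metrics have
# genuine edges to measure. No scanner physics is modelled.

# Standard deviation of the background texture, gray levels. Kept modest so
# the lesion/background histogram modes stay separable at typical contrasts.
.TEXTURE_SD <- 4

#' Generate a clean lesion phantom
#'
#' Builds a deterministic synthetic grayscale image from a [PhantomSpec-class]:
#' a smooth background (white noise low-pass filtered at `textureScale`) around
#' `backgroundLevel`, with `nLesions` soft-edged ellipses offset by
#' `lesionContrast`. Lesions lie fully inside the image. The same spec always
#' produces the same pixels.
#'
#' @param spec a [PhantomSpec-class].
#' @return a numeric matrix (`height` x `width`) of gray levels in [0, 255].
#' @examples
#' img <- generatePhantom(PhantomSpec(64, 64, nLesions = 2, seed = 7))
#' dim(img)
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@height
  w <- spec@width
  withr::with_seed(spec@seed, {
    if (is.finite(spec@textureScale)) {
      tex <- gaussianSmooth(matrix(stats::rnorm(h * w), h, w),
                            spec@textureScale)
      s <- stats::sd(tex)
      tex <- if (s > 0) tex / s * .TEXTURE_SD else tex * 0
    } else {
      tex <- matrix(0, h, w)
    }
    img <- spec@backgroundLevel + tex
    if (spec@nLesions > 0L) {
      rowIdx <- matrix(seq_len(h), h, w)
      colIdx <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (k in seq_len(spec@nLesions)) {
        # semi-axes between 8% and 18% of the short image side
        ax <- stats::runif(1, 0.08, 0.18) * min(h, w)
        ay <- stats::runif(1, 0.08, 0.18) * min(h, w)
        margin <- max(ax, ay) + 3
        if (2 * margin >= min(h, w)) {
          ax <- ay <- max(min(h, w) / 6, 1.5)
          margin <- max(ax, ay) + 1
        }
        cy <- stats::runif(1, margin, h - margin)
        cx <- stats::runif(1, margin, w - margin)
        th <- stats::runif(1, 0, pi)
        dy <- rowIdx - cy
        dx <- colIdx - cx
        u <- cos(th) * dx + sin(th) * dy
        v <- -sin(th) * dx + cos(th) * dy
        d <- sqrt((u / ax)^2 + (v / ay)^2)   # 1 on the lesion boundary
        # soft edge approximately 1.5 px wide at the boundary
        soft <- 1.5 / mean(c(ax, ay))
        mask <- stats::plogis((1 - d) / soft)
        img <- img + spec@lesionContrast * mask
      }
    }
  })
  # texture tails may poke past the valid range by a few gray levels
  pmin(pmax(img, 0), 255)
}

#' Corrupt an image with multiplicative speckle
#'
#' Applies fully developed multiplicative speckle: each pixel is multiplied by
#' an i.i.d. Gamma(shape = looks, rate = looks) draw, a unit-mean field with
#' variance `1/looks`. `looks = Inf` is the zero-variance limit and returns
#' the input unchanged. Output is not clipped, so the noise statistics remain
#' exact; clipping happens only on file export.
#'
#' @param img numeric matrix, clean image.
#' @param spec a [NoiseSpec-class] with `kind = "speckle"`.
#' @return corrupted image, same shape.
#' @examples
#' img <- matrix(100, 64, 64)
#' noisy <- addSpeckle(img, NoiseSpec("speckle", looks = 4, seed = 1))
#' @export
addSpeckle <- function(img, spec) {
  assertImage(img)
  stopifnot(is(spec, "NoiseSpec"))
  if (spec@kind != "speckle") stop("spec$kind must be 'speckle'", call. = FALSE)
  if (!(spec@looks > 0)) stop("looks must be > 0", call. = FALSE)
  if (is.infinite(spec@looks)) return(img)
  withr::with_seed(spec@seed, {
    n <- matrix(stats::rgamma(length(img), shape = spec@looks,
                              rate = spec@looks),
                nrow(img), ncol(img))
  })
  img * n
}

#' Corrupt an image with additive white Gaussian noise at a target SNR
#'
#' Adds zero-mean Gaussian noise with variance `P / 10^(snrDb/10)` where `P`
#' is the mean squared intensity of `img`, so the realized SNR matches the
#' target up to sampling error. `snrDb = Inf` returns the input unchanged.
#'
#' @param img numeric matrix with nonzero signal power.
#' @param spec a [NoiseSpec-class] with `kind = "awgn"`.
#' @return corrupted image, same shape (not clipped).
#' @examples
#' img <- generatePhantom(PhantomSpec(64, 64, seed = 1))
#' noisy <- addAwgnAtSnr(img, NoiseSpec("awgn", snrDb = 25, seed = 2))
#' @export
addAwgnAtSnr <- function(img, spec) {
  assertImage(img)
  stopifnot(is(spec, "NoiseSpec"))
  if (spec@kind != "awgn") stop("spec$kind must be 'awgn'", call. = FALSE)
  power <- mean(img^2)
  if (power == 0) stop("SNR undefined for an all-zero image", call. = FALSE)
  if (is.infinite(spec@snrDb)) return(img)
  sigma <- sqrt(power / 10^(spec@snrDb / 10))
  withr::with_seed(spec@seed, {
    noise <- matrix(stats::rnorm(length(img), sd = sigma),
                    nrow(img), ncol(img))
  })
  img + noise
}

# Apply whichever corruption a NoiseSpec requests.
applyNoise <- function(img, spec) {
  if (spec@kind == "speckle") addSpeckle(img, spec) else addAwgnAtSnr(img, spec)
}

#' Generate a seeded train/test corpus of (clean, noisy) phantom pairs
#'
#' Emulates a study corpus split into training and held-out test images
#' (defaults 800/200). Every phantom and every noise realization draws its
#' own sub-seed deterministically from `seed`, so splits are reproducible and
#' all clean images are pairwise distinct.
#'
#' @param nTrain,nTest number of training and test pairs (>= 1).
#' @param phantomSpec a [PhantomSpec-class]; its `seed` slot is ignored in
#'   favour of per-image sub-seeds.
#' @param noiseSpec a [NoiseSpec-class]; its `seed` slot is likewise replaced
#'   per image.
#' @param seed master integer seed.
#' @return a list with elements `train` and `test`, each a list of
#'   `list(clean = matrix, noisy = matrix)` pairs.
#' @examples
#' ds <- makeDataset(4, 2, PhantomSpec(48, 48), NoiseSpec("speckle", 4),
#'                   seed = 0)
#' length(ds$train)
#' @export
makeDataset <- function(nTrain = 800L, nTest = 200L,
                        phantomSpec = PhantomSpec(),
                        noiseSpec = NoiseSpec("speckle", looks = 4),
                        seed = 0L) {
  stopifnot(nTrain >= 1L, nTest >= 1L)
  nTotal <- nTrain + nTest
  subSeeds <- withr::with_seed(seed,
                               sample.int(.Machine$integer.max - 1L,
                                          2L * nTotal))
  makePair <- function(i) {
    ps <- phantomSpec
    ps@seed <- subSeeds[2L * i - 1L]
    ns <- noiseSpec
    ns@seed <- subSeeds[2L * i]
    clean <- generatePhantom(ps)
    list(clean = clean, noisy = applyNoise(clean, ns))
  }
  list(train = lapply(seq_len(nTrain), makePair),
       test = lapply(nTrain + seq_len(nTest), makePair))
}
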