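# Guided-filter detail enhancement, the spatial high-pass correction, and the
# three-step preprocessing pipeline that chains them after the contrast stage.
#
# The guided filter is implemented twice, deliberately: a fast box-filter
# formulation (guidedFilter) and an explicit per-pixel-pair kernel evaluation
# (guidedFilterBruteForce) used as an independent oracle in tests. Both use
# border-truncated windows centred at every pixel, so they agree to floating-
# point precision.

#' Guided filter
#'
#' Edge-preserving smoothing in which each output pixel is a local linear
#' function of the guide image. For every window `r` of half-width `radius`,
#' `a_r = cov(guide, input) / (var(guide) + epsilon)` and
#' `b_r = mean(input) - a_r * mean(guide)`; the output at pixel `i` averages
#' `a_r * guide_i + b_r` over all windows containing `i`. Windows are
#' truncated at image borders. Intensities are rescaled to [0, 1] internally,
#' so `epsilon` lives on that scale.
#'
#' @param input numeric matrix, the image to filter.
#' @param guide numeric matrix, the guidance image (same shape; self-guided
#'   filtering passes the image itself).
#' @param params a [GuidedFilterParams-class].
#' @return filtered image, same shape.
#' @examples
#' img <- generatePhantom(PhantomSpec(48, 48, seed = 1))
#' smooth <- guidedFilter(img, img, GuidedFilterParams(radius = 2))
#' @export
guidedFilter <- function(input, guide, params = GuidedFilterParams()) {
  assertImage(input)
  assertImage(guide)
  assertSameShape(input, guide)
  stopifnot(is(params, "GuidedFilterParams"))
  r <- params@radius
  if (2L * r + 1L > min(nrow(input), ncol(input))) {
    stop("guided-filter window larger than the image", call. = FALSE)
  }
  I <- guide / 255
  p <- input / 255
  eps <- params@epsilon
  N <- boxCount(nrow(I), ncol(I), r)
  mI <- boxSum(I, r) / N
  mP <- boxSum(p, r) / N
  varI <- boxSum(I * I, r) / N - mI^2
  covIP <- boxSum(I * p, r) / N - mI * mP
  a <- covIP / (varI + eps)
  b <- mP - a * mI
  q <- (boxSum(a, r) / N) * I + boxSum(b, r) / N
  q * 255
}

#' Explicit guided-filter kernel matrix
#'
#' Builds the full `n x n` filter kernel `W` (n = number of pixels) such that
#' `vec(output) = W %*% vec(input)`:
#' `W[i, j] = (1/N_i) * sum over windows r containing both i and j of
#' (1 + (I_i - mu_r)(I_j - mu_r) / (sigma_r^2 + eps)) / |w_r|`,
#' with `N_i` the number of windows containing `i`. Every row sums to 1.
#' Intended for small images only (the matrix is dense).
#'
#' @param guide numeric matrix, guidance image.
#' @param params a [GuidedFilterParams-class].
#' @return dense numeric matrix of size `length(guide)` squared, columns and
#'   rows in column-major pixel order.
#' @export
guidedFilterKernel <- function(guide, params = GuidedFilterParams()) {
  assertImage(guide)
  stopifnot(is(params, "GuidedFilterParams"))
  h <- nrow(guide)
  w <- ncol(guide)
  n <- h * w
  if (n > 4096L) {
    stop("guidedFilterKernel is intended for small images (<= 64x64)",
         call. = FALSE)
  }
  r <- params@radius
  if (2L * r + 1L > min(h, w)) {
    stop("guided-filter window larger than the image", call. = FALSE)
  }
  I <- as.vector(guide) / 255
  eps <- params@epsilon
  W <- matrix(0, n, n)
  for (ci in seq_len(h)) {
    for (cj in seq_len(w)) {
      rows <- max(1L, ci - r):min(h, ci + r)
      cols <- max(1L, cj - r):min(w, cj + r)
      idx <- as.vector(outer(rows, cols, function(a, b) (b - 1L) * h + a))
      Iv <- I[idx]
      mu <- mean(Iv)
      v <- mean(Iv^2) - mu^2
      dev <- Iv - mu
      W[idx, idx] <- W[idx, idx] +
        (1 + outer(dev, dev) / (v + eps)) / length(idx)
    }
  }
  W / as.vector(boxCount(h, w, r))
}

#' Brute-force guided filter (test oracle)
#'
#' Evaluates the guided filter by explicit kernel-matrix multiplication via
#' [guidedFilterKernel()]. Mathematically identical to [guidedFilter()] but
#' computed along a completely different route; O(n^2) memory, so use small
#' images (<= 32x32 advised).
#'
#' @inheritParams guidedFilter
#' @return filtered image, same shape.
#' @export
guidedFilterBruteForce <- function(input, guide,
                                   params = GuidedFilterParams()) {
  assertImage(input)
  assertImage(guide)
  assertSameShape(input, guide)
  W <- guidedFilterKernel(guide, params)
  matrix(W %*% as.vector(input), nrow(input), ncol(input))
}

#' Detail enhancement
#'
#' Boosts the detail layer (original minus smoothed base) by the gain `F`:
#' `output = base + F * (original - base)`. `F = 1` returns the original,
#' `F = 0` the base; gains above 1 amplify detail.
#'
#' @param original numeric matrix, the un-smoothed image.
#' @param base numeric matrix, the smoothed base layer (same shape).
#' @param detailGain non-negative gain F.
#' @return enhanced image, same shape.
#' @export
detailEnhance <- function(original, base, detailGain = 2) {
  assertImage(original)
  assertImage(base)
  assertSameShape(original, base)
  stopifnot(is.numeric(detailGain), length(detailGain) == 1L, detailGain >= 0)
  base + detailGain * (original - base)
}

#' The 3x3 spatial high-pass kernel
#'
#' @return the normalized kernel matrix
#'   `[[-2,-1,-2],[-1,18,-1],[-2,-1,-2]] / 17`; its coefficients sum to 6/17.
#' @export
highpassKernel <- function() {
  matrix(c(-2, -1, -2,
           -1, 18, -1,
           -2, -1, -2), 3L, 3L, byrow = TRUE) / 17
}

#' Spatial high-pass correction
#'
#' Convolves the image with the fixed 3x3 high-pass template (see
#' [highpassKernel()]) using reflective border padding. Applied after detail
#' enhancement to correct the over-sharpening that the detail boost can
#' introduce; a constant image of value `v` maps to the constant `6/17 * v`.
#'
#' @param img numeric matrix, at least 3x3.
#' @return filtered image, same shape.
#' @export
highpassFilter <- function(img) {
  assertImage(img, minDim = 3L)
  convolveReflect(img, highpassKernel())
}

#' Three-step preprocessing pipeline
#'
#' Chains the despeckling front end: (1) piecewise contrast enhancement from
#' the global grayscale mean, (2) self-guided filtering plus detail boost with
#' gain F, (3) spatial high-pass correction. The three intermediate images are
#' attached as the `"intermediates"` attribute (named `contrast`, `detail`,
#' `highpass`) for inspection.
#'
#' @param img numeric matrix, input image.
#' @param contrastParams a [ContrastParams-class].
#' @param guidedParams a [GuidedFilterParams-class]; its `detailGain` slot is
#'   the boost F.
#' @return preprocessed image with attribute `"intermediates"`.
#' @examples
#' img <- generatePhantom(PhantomSpec(48, 48, seed = 1))
#' out <- preprocessImage(img)
#' names(attr(out, "intermediates"))
#' @export
preprocessImage <- function(img, contrastParams = ContrastParams(),
                            guidedParams = GuidedFilterParams()) {
  assertImage(img)
  h <- piecewiseContrast(img, contrastParams)
  base <- guidedFilter(h, h, guidedParams)
  detail <- detailEnhance(h, base, guidedParams@detailGain)
  out <- highpassFilter(detail)
  attr(out, "intermediates") <- list(contrast = h, detail = detail,
                                     highpass = out)
  out
}
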