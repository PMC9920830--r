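# Grayscale-mean-driven piecewise contrast enhancement. One branch is chosen
# for the whole image from its global mean: dark images are stretched with a
# logarithmic transform, mid-tone images pass unchanged, bright images are
# stretched with an exponential transform. Both transforms are strictly
# monotone, so pixel rank order is preserved.

#' Global grayscale mean of an image
#'
#' @param img numeric matrix.
#' @return arithmetic mean of all pixels.
#' @export
grayscaleMean <- function(img) {
  assertImage(img)
  mean(img)
}

#' Logarithmic contrast transform
#'
#' Computes `a * (ln(1 + f))^b + c` pixelwise, enlarging the lower gray-value
#' interval and compressing the upper one. With the default endpoint-
#' normalized coefficients (`a = 255/ln(256)`, `b = 1`, `c = 0`), 0 maps to 0
#' and 255 maps to 255.
#'
#' @param img numeric matrix with non-negative pixels.
#' @param params a [ContrastParams-class].
#' @return transformed image, same shape.
#' @export
logTransform <- function(img, params = ContrastParams()) {
  assertImage(img)
  stopifnot(is(params, "ContrastParams"))
  if (any(img < 0)) {
    stop("logTransform requires non-negative pixel values", call. = FALSE)
  }
  params@aLog * log1p(img)^params@bLog + params@cLog
}

#' Exponential contrast transform
#'
#' Computes `a * (b^(f/255) - 1) + c` pixelwise, the counterpart of
#' [logTransform()] for overly bright images. With the defaults (`b = 256`,
#' `a = 255/(b-1) = 1`, `c = 0`) it is the exact inverse of the default
#' logarithmic transform.
#'
#' @inheritParams logTransform
#' @return transformed image, same shape.
#' @export
expTransform <- function(img, params = ContrastParams()) {
  assertImage(img)
  stopifnot(is(params, "ContrastParams"))
  params@aExp * (params@bExp^(img / 255) - 1) + params@cExp
}

#' Piecewise contrast enhancement driven by the grayscale mean
#'
#' Selects one transform for the whole image from its global mean N: the log
#' branch for N in [0, tLow), the identity for N in [tLow, tHigh), and the
#' exp branch for N in [tHigh, tMax). Means at or above `tMax` (default 260)
#' are outside the supported domain and rejected.
#'
#' @inheritParams logTransform
#' @return enhanced image, same shape; returned unchanged on the identity
#'   branch.
#' @examples
#' img <- matrix(150, 8, 8)
#' identical(piecewiseContrast(img), img)  # identity branch
#' @export
piecewiseContrast <- function(img, params = ContrastParams()) {
  assertImage(img)
  stopifnot(is(params, "ContrastParams"))
  m <- mean(img)
  if (m < 0 || m >= params@tMax) {
    stop(sprintf("grayscale mean %.2f outside the supported domain [0, %g)",
                 m, params@tMax), call. = FALSE)
  }
  if (m < params@tLow) {
    logTransform(img, params)
  } else if (m < params@tHigh) {
    img
  } else {
    expTransform(img, params)
  }
}
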