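# Shared low-level image helpers: validation, reflective padding, small-kernel
# convolution and O(1)-per-pixel windowed sums (integral images). All public
# functions in the package represent a grayscale image as a numeric matrix in
# gray-level units (nominal range [0, 255]; values may transiently leave that
# range between pipeline stages).

assertImage <- function(img, arg = deparse(substitute(img)), minDim = 1L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("'%s' must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  }
  if (nrow(img) < minDim || ncol(img) < minDim) {
    stop(sprintf("'%s' must be at least %dx%d pixels", arg, minDim, minDim),
         call. = FALSE)
  }
  if (!all(is.finite(img))) {
    stop(sprintf("'%s' contains non-finite pixel values", arg), call. = FALSE)
  }
  invisible(img)
}

assertSameShape <- function(a, b,
                            argA = deparse(substitute(a)),
                            argB = deparse(substitute(b))) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("'%s' (%dx%d) and '%s' (%dx%d) must have identical shape",
                 argA, nrow(a), ncol(a), argB, nrow(b), ncol(b)),
         call. = FALSE)
  }
  invisible(NULL)
}

# Edge-inclusive mirror index for reflective padding of one dimension.
reflectIndex <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (p >= n) stop("reflection padding wider than the image", call. = FALSE)
  c(p:1, seq_len(n), n:(n - p + 1L))
}

padReflect <- function(img, pRow, pCol = pRow) {
  img[reflectIndex(nrow(img), pRow), reflectIndex(ncol(img), pCol),
      drop = FALSE]
}

# 2-D convolution with an odd-sized kernel and reflective border handling.
# Kernel is applied as a sliding dot product; every kernel used in the package
# is 180-degree symmetric, so convolution and correlation coincide.
convolveReflect <- function(img, kernel) {
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  if (kh %% 2L == 0L || kw %% 2L == 0L) {
    stop("kernel dimensions must be odd", call. = FALSE)
  }
  if (kh > nrow(img) || kw > ncol(img)) {
    stop("image smaller than the kernel", call. = FALSE)
  }
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  pad <- padReflect(img, ph, pw)
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      if (kernel[u, v] != 0) {
        out <- out + kernel[u, v] * pad[u:(u + h - 1L), v:(v + w - 1L)]
      }
    }
  }
  out
}

# Separable Gaussian smoothing (used by the phantom generator's background
# texture). Kernel radius is 3 sigma, truncated to fit the image.
gaussianSmooth <- function(img, sigma) {
  if (!is.finite(sigma) || sigma <= 0) return(img)
  r <- min(ceiling(3 * sigma), (nrow(img) - 1L) %/% 2L,
           (ncol(img) - 1L) %/% 2L)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  tmp <- convolveReflect(img, matrix(k, ncol = 1L))
  convolveReflect(tmp, matrix(k, nrow = 1L))
}

# Sum of img over the (2*radius+1)^2 window centred at each pixel, truncated at
# image borders, via an integral image.
boxSum <- function(img, radius) {
  h <- nrow(img)
  w <- ncol(img)
  S <- rbind(0, apply(img, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  r1 <- pmax(seq_len(h) - radius, 1L)
  r2 <- pmin(seq_len(h) + radius, h)
  c1 <- pmax(seq_len(w) - radius, 1L)
  c2 <- pmin(seq_len(w) + radius, w)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Number of in-image pixels in each truncated window.
boxCount <- function(h, w, radius) {
  boxSum(matrix(1, h, w), radius)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
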