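# Image-quality metrics for despeckling: MSE, SNR, PSNR, the edge
# preservation index (EPI, also called border protection index), a
# false-recognition rate, and the summed destruction time. Directional
# metrics take the reference image as their first argument.

#' Mean squared error between two images
#'
#' @param a,b numeric matrices of identical shape.
#' @return mean of squared pixel differences (squared gray levels).
#' @export
mseImage <- function(a, b) {
  assertImage(a)
  assertImage(b)
  assertSameShape(a, b)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(maxIntensity^2 / mse(a, b))` in decibels; `Inf` when the
#' images are identical.
#'
#' @param a,b numeric matrices of identical shape.
#' @param maxIntensity peak intensity of the image format (255 for 8-bit).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 4, 4), matrix(255, 4, 4))  # 0 dB
#' @export
psnr <- function(a, b, maxIntensity = 255) {
  m <- mseImage(a, b)
  if (m == 0) return(Inf)
  10 * log10(maxIntensity^2 / m)
}

#' Signal-to-noise ratio of a test image against a reference
#'
#' Defined as reference power over error power,
#' `10 * log10(mean(reference^2) / mse(reference, test))`, in decibels.
#' Directional: the first argument is the reference.
#'
#' @param reference numeric matrix with nonzero power.
#' @param test numeric matrix, same shape.
#' @return SNR in dB; `Inf` when the images are identical.
#' @export
snrDb <- function(reference, test) {
  assertImage(reference)
  assertImage(test)
  assertSameShape(reference, test)
  power <- mean(reference^2)
  if (power == 0) stop("reference image has zero power", call. = FALSE)
  m <- mean((reference - test)^2)
  if (m == 0) return(Inf)
  10 * log10(power / m)
}

# 5-point discrete Laplacian with reflective borders.
laplacian <- function(img) {
  convolveReflect(img, matrix(c(0, 1, 0,
                                1, -4, 1,
                                0, 1, 0), 3L, 3L, byrow = TRUE))
}

#' Edge preservation index
#'
#' Normalized correlation of Laplacian deviations between a reference image
#' and a processed image:
#' `sum((La - mean(La)) * (Lb - mean(Lb))) / sqrt(sum((La - mean(La))^2) *
#' sum((Lb - mean(Lb))^2))` with `L` the 5-point discrete Laplacian. Bounded
#' in [-1, 1]; 1 means edges perfectly retained, invariant to adding a
#' constant to either image and to positive rescaling of both.
#'
#' @param preImg numeric matrix, reference (before processing).
#' @param postImg numeric matrix, processed image (same shape).
#' @return EPI in [-1, 1].
#' @examples
#' img <- generatePhantom(PhantomSpec(48, 48, seed = 1))
#' epi(img, img)  # 1
#' @export
epi <- function(preImg, postImg) {
  assertImage(preImg)
  assertImage(postImg)
  assertSameShape(preImg, postImg)
  da <- laplacian(preImg)
  db <- laplacian(postImg)
  da <- da - mean(da)
  db <- db - mean(db)
  na2 <- sum(da^2)
  nb2 <- sum(db^2)
  if (na2 == 0 || nb2 == 0) {
    stop("EPI undefined for an image with constant Laplacian", call. = FALSE)
  }
  sum(da * db) / sqrt(na2 * nb2)
}

#' False-recognition rate
#'
#' Fraction of pixels whose absolute deviation from the reference exceeds a
#' tolerance (default 5 gray levels). A pixel-exceedance interpretation of a
#' per-pixel misidentification rate.
#'
#' @param pred numeric matrix, predicted/denoised image.
#' @param target numeric matrix, reference (same shape).
#' @param tolGray tolerance in gray levels.
#' @return fraction in [0, 1].
#' @export
falseRecognitionRate <- function(pred, target, tolGray = 5) {
  assertImage(pred)
  assertImage(target)
  assertSameShape(pred, target)
  stopifnot(tolGray >= 0)
  mean(abs(pred - target) > tolGray)
}

#' Total destruction time
#'
#' Sums per-stage wall-clock times into the total despeckling time.
#'
#' @param stageTimes numeric vector of non-negative stage durations (seconds);
#'   may be empty.
#' @return total time in seconds.
#' @export
destructionTime <- function(stageTimes) {
  if (length(stageTimes) == 0L) return(0)
  stopifnot(is.numeric(stageTimes))
  if (any(!is.finite(stageTimes)) || any(stageTimes < 0)) {
    stop("stage times must be finite and non-negative", call. = FALSE)
  }
  sum(stageTimes)
}

#' Evaluate a denoising result
#'
#' Fills an [EvalReport-class] comparing a denoised image against its clean
#' reference: MSE, SNR and PSNR of denoised vs clean, EPI of clean vs
#' denoised, false-recognition rate, and the summed stage times.
#'
#' @param clean numeric matrix, ground-truth image.
#' @param noisy numeric matrix, corrupted input (same shape; retained for
#'   protocol completeness and shape checking).
#' @param denoised numeric matrix, the despeckled output (same shape).
#' @param stageTimes numeric vector of stage durations in seconds.
#' @param tolGray tolerance for the false-recognition rate, gray levels.
#' @return an [EvalReport-class].
#' @examples
#' img <- generatePhantom(PhantomSpec(48, 48, seed = 1))
#' noisy <- addSpeckle(img, NoiseSpec("speckle", looks = 4, seed = 2))
#' evaluateDenoising(img, noisy, noisy)
#' @export
evaluateDenoising <- function(clean, noisy, denoised,
                              stageTimes = numeric(), tolGray = 5) {
  assertImage(clean)
  assertImage(noisy)
  assertImage(denoised)
  assertSameShape(clean, noisy)
  assertSameShape(clean, denoised)
  m <- mseImage(denoised, clean)
  new("EvalReport",
      mse = m,
      snrDb = snrDb(clean, denoised),
      psnrDb = psnr(clean, denoised),
      epi = epi(clean, denoised),
      falseRecognitionRate = falseRecognitionRate(denoised, clean, tolGray),
      tDes = destructionTime(stageTimes))
}

#' Serialize an evaluation report to JSON
#'
#' Writes the report as a flat JSON object. Infinite PSNR/SNR values are
#' stored as the string `"Inf"` and restored on read, so the round trip is
#' lossless.
#'
#' @param report an [EvalReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  vals <- reportAsList(report)
  vals <- lapply(vals, function(v) if (is.infinite(v)) "Inf" else v)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn writeReport Read a report back from its JSON file.
#' @export
readReport <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- lapply(vals, function(v) if (identical(v, "Inf")) Inf else v)
  new("EvalReport", mse = as.numeric(vals$mse), snrDb = as.numeric(vals$snrDb),
      psnrDb = as.numeric(vals$psnrDb), epi = as.numeric(vals$epi),
      falseRecognitionRate = as.numeric(vals$falseRecognitionRate),
      tDes = as.numeric(vals$tDes))
}
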