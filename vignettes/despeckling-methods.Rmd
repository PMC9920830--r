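---
title: "Methods: speckle destruction for breast ultrasound images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle destruction for breast ultrasound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(despeckle)
```

## The problem

Coherent ultrasound imaging produces speckle: granular, multiplicative
interference noise that lowers effective resolution and can mask small
breast lesions. Removing it is harder than removing additive noise because
the noise amplitude scales with the signal, and because clinical value lives
in exactly the structures — lesion boundaries — that aggressive smoothing
destroys first. This package implements a despeckling pipeline whose every
stage is tunable and testable:

1. **Piecewise contrast enhancement.** One transform is chosen for the whole
   image from its global grayscale mean $N$: a logarithmic stretch
   $h = a\,(\ln(1+f))^{b} + c$ for dark images ($N < 100$), the identity for
   mid-tone images ($100 \le N < 180$), and an exponential stretch
   $h = a\,(b^{f/255} - 1) + c$ for bright ones ($180 \le N < 260$). Means at
   or above 260 are rejected as out of domain.
2. **Guided-filter detail boost.** The contrast-enhanced image is smoothed by
   a self-guided filter (each output pixel a local linear function of the
   guide), and the detail layer is re-amplified:
   $I' = \mathrm{base} + F\,(\mathrm{orig} - \mathrm{base})$.
3. **Spatial high-pass correction.** A fixed $3\times3$ template
   $\frac{1}{17}\begin{pmatrix}-2&-1&-2\\-1&18&-1\\-2&-1&-2\end{pmatrix}$
   is convolved over the boosted image to correct the over-sharpening the
   detail boost can introduce.
4. **Learned residual denoising.** A compact recurrent-convolutional network
   predicts the noise field of each $32\times32$ patch and subtracts it,
   trained under a composite loss whose edge term penalizes
   vertical-gradient mismatch so that lesion boundaries survive smoothing.

## The denoiser

The network is deliberately small (1825 parameters at the default
configuration): a $5\times5$ convolution producing 8 feature maps; a
"logical pool" branch that max-pools those maps $2\times2$ and re-upsamples
them (nearest neighbour), giving every refinement step access to a
locally-dominant, translation-tolerant summary; three *weight-shared*
$5\times5$ convolutional refinement steps (the recurrence); and a $1\times1$
mixing layer that outputs the predicted noise. The output layer is
zero-initialized, so an untrained model is exactly the identity — a useful
fixed point for testing and a safe starting point for optimization.

Training minimizes, over patches sampled from (clean, noisy) pairs,

$$\mathcal{L} = w_{\mathrm{adv}}\,\mathcal{L}_{\mathrm{adv}}
  + w_{1}\,\mathbb{E}\,|P - T|
  + \beta\,\mathbb{E}\,|\Delta_v P - \Delta_v T|,$$

where $\Delta_v$ is the vertical first finite difference,
$P$ the prediction and $T$ the clean target. Vertical gradients are singled
out because breast anatomy layers tissue interfaces roughly horizontally in
standard probe orientation, so the vertical direction carries the dominant
edge structure. The edge term is a pseudometric (invariant to additive
constants), which is what one wants: it scores edge *shape*, not intensity
offset. Defaults are $w_1 = 1$, $\beta = 0.1$, $w_{\mathrm{adv}} = 0$.

An adversarial term is available behind `advWeight`: a least-squares
objective against a small 3-layer patch critic. It is off by default —
adversarial training needs careful schedule tuning to be a net win, and the
L1 + edge objective alone trains stably and reproducibly, which we value
more here.

Optimization uses Adam at learning rate $10^{-3}$. All randomness (weight
initialization, patch sampling) flows from explicit integer seeds;
repeating a training run with the same seeds reproduces the same weights to
floating-point accuracy on a fixed BLAS.

Full images are denoised by tiling into overlapping patches (stride half a
patch), with overlaps blended by averaging; the blending weights sum to one
everywhere, so a constant image passes through an identity model unchanged.

## The phantom generator

Clinical image corpora cannot ship with a package, so validation runs on
synthetic phantoms that reproduce the two features the pipeline is judged
on: *smooth tissue-like background* (white noise low-pass filtered at a
`textureScale` of 8 px, standard deviation 4 gray levels) and *genuine
edges* (elliptical lesions with a logistic edge profile about 1.5 px wide,
offset from background by `lesionContrast`). Defaults — $128\times128$
pixels, background 120, contrast +60, three lesions — keep both histogram
modes safely inside [0, 255].

The corruption models are exact by construction:

* **Speckle**: fully developed multiplicative speckle, pixelwise
  multiplication by i.i.d. $\mathrm{Gamma}(L, L)$ draws — unit mean,
  variance $1/L$ — the standard looks-parameterized model for coherent
  imaging. Four looks is the default study condition.
* **AWGN**: zero-mean Gaussian noise with variance
  $\overline{f^2} / 10^{\mathrm{SNR}/10}$, hitting target SNRs (25/45/65 dB
  are the tested levels) up to sampling error.

Corrupted images are *not* clipped to [0, 255] internally — clipping would
bias the noise moments the tests calibrate against — only on file export.

What the phantoms do **not** model: scanner physics (point-spread function,
log compression, attenuation, shadowing), anatomical texture statistics,
and the spatial correlation of real speckle. Passing the synthetic suite
therefore demonstrates that the algorithms are implemented correctly and
behave as designed under the stated noise models; it does not certify
clinical performance on scanner data.

## Metrics

MSE, SNR ($10\log_{10}$ of reference power over error power), PSNR
($10\log_{10}(255^2/\mathrm{MSE})$), and a false-recognition rate (fraction
of pixels deviating more than 5 gray levels — a pixel-exceedance reading of
a per-pixel misidentification rate, since no formal definition is standard).
Edge retention is scored by the edge preservation index: the normalized
correlation of Laplacian deviations,

$$\mathrm{EPI} = \frac{\sum (\nabla a - \overline{\nabla a})(\nabla b -
\overline{\nabla b})}{\sqrt{\sum (\nabla a - \overline{\nabla a})^2
\sum (\nabla b - \overline{\nabla b})^2}},$$

with $\nabla$ the 5-point Laplacian. This correlation form is bounded in
$[-1, 1]$, invariant to intensity offset and joint rescaling, and equals 1
exactly when edges are perfectly retained. Note its behaviour on smooth
phantoms: because the clean Laplacian is weak (soft edges, smooth texture)
while any residual noise has a strong Laplacian, absolute EPI values stay
small until denoising is nearly perfect. Comparisons *between* methods at
equal budgets remain meaningful, and that is how the test suite uses it.
On clinical images with strong interfaces, absolute values are much higher.
Total "destruction time" is the plain sum of per-stage wall times, recorded
by the pipeline runner into every manifest.

## Numerical choices

* **Borders**: reflective (edge-inclusive) padding for all classical filters
  (high-pass, Laplacian, Gaussian texture smoothing); zero padding inside
  the CNN, the convention of residual denoisers.
* **Guided filter windows** are truncated at image borders and normalized by
  the true pixel count, which makes the fast box-filter path agree with the
  explicit kernel definition to machine precision — the package carries
  both implementations and tests their equality ($<10^{-8}$) as a standing
  oracle.
* **Epsilon scale**: the guided filter rescales intensities to [0, 1]
  internally, so `epsilon` (default 0.01) is comparable across bit depths.
* **Contrast defaults** are endpoint-normalized ($a_{\log} = 255/\ln 256$,
  $b_{\exp} = 256$, $a_{\exp} = 1$), mapping [0, 255] onto itself; the
  default exponential transform is the exact inverse of the default
  logarithmic one.
* **Max-pool ties** resolve to the first (column-major) maximum; gradients
  route only to the argmax pixel.
* **Degenerate inputs** are rejected with specific errors rather than
  silently coerced: all-zero images for SNR, constant-Laplacian images for
  EPI, images smaller than a kernel or patch, negative pixels for the log
  transform, grayscale means at or above 260.

## Problem sizes in the shipped tests

The test and acceptance suites run the full pipeline at sizes chosen to
exercise every code path while staying desk-scale: 256 × 256 fields for
noise-moment calibration; 200 patch pairs of 32 × 32 and 100 iterations for
the training-convergence check; and, for the end-to-end and ablation
checks, 12 training plus 20 held-out 64 × 64 two-lesion phantoms at 4
looks with 300 training iterations per model. These mirror, at reduced
scale, a conventional 800/200 train/test corpus split, which remains the
`makeDataset()` default.

## Design decisions that were genuinely open

* **Speckle distribution.** No distribution is mandated by the looks
  parameterization alone; Gamma-by-looks is the standard fully-developed
  speckle model and gives closed-form moments the tests can calibrate
  against.
* **Network output shape.** A patch-to-patch residual architecture was
  chosen over a patch-to-scalar one: it is the only reading under which a
  pooling CNN can return a full denoised image, and it retains the printed
  layer sizes (8 maps, 32 patch, 5 kernel, 2 pool).
* **Recurrence** is realized as unrolled weight sharing (3 steps), the
  simplest recurrence over a static image.
* **Edge-loss prefactor.** A multiplicative $\log$-intensity prefactor on
  the edge term was considered and dropped: it is sign-indefinite for
  intensities below 1 and couples the loss scale to preprocessing output,
  harming stability while adding no modelling value. The vertical-gradient
  L1 core is kept.
* **EPI form.** A difference-of-ratios variant of the index is unbounded
  and cannot support fixed thresholds; the correlation form above, using
  the same Laplacian-deviation ingredients, is adopted.
* **Branch thresholds** 100/180/260 are fixed defaults but config-exposed,
  as are all loss weights and filter parameters, since reasonable values
  are application-dependent.

## Limitations

* The denoiser is intentionally tiny and CPU-trainable; it will not match
  large GPU-trained denoisers on natural images.
* Training on synthetic phantoms transfers to clinical data only insofar as
  the noise model matches; domain fine-tuning is expected.
* EPI on smooth synthetic phantoms is a relative, not absolute, measure
  (see above).
* The adversarial path is functional but unexercised by default; no claim
  is made about its benefit.
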