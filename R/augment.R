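# Stochastic view generation for self-supervised pretraining. All transforms
# preserve image size and the [0, 1] intensity range (values pushed outside
# are clamped; clamping a handful of pixels is part of the jitter, a large
# clipped fraction triggers a warning).

#' Augmentation policy
#'
#' Grayscale-safe transform ranges for B-mode images: random resized crop,
#' horizontal flip, brightness/contrast jitter, Gaussian blur and
#' multiplicative speckle jitter. Color transforms are deliberately absent.
#'
#' @param crop_scale Range of the area-side fraction kept by the random crop
#'   (the crop is resized back to the original size).
#' @param flip_prob Probability of a horizontal flip.
#' @param brightness Max absolute additive intensity shift.
#' @param contrast Max relative contrast change about the image mean.
#' @param blur_sigma Range of the Gaussian blur sigma, pixels; draws below
#'   0.05 skip the blur.
#' @param speckle_jitter Strength of multiplicative pixel noise.
#' @return A list of class `augmentation_policy`.
#' @export
augmentation_policy <- function(crop_scale = c(0.6, 1.0), flip_prob = 0.5,
                                brightness = 0.2, contrast = 0.2,
                                blur_sigma = c(0.1, 1.0),
                                speckle_jitter = 0.15) {
  structure(list(crop_scale = crop_scale, flip_prob = flip_prob,
                 brightness = brightness, contrast = contrast,
                 blur_sigma = blur_sigma, speckle_jitter = speckle_jitter),
            class = "augmentation_policy")
}

#' The identity augmentation policy
#'
#' @return A policy under which `make_views` returns the input unchanged.
#' @export
identity_policy <- function() {
  augmentation_policy(crop_scale = c(1, 1), flip_prob = 0, brightness = 0,
                      contrast = 0, blur_sigma = c(0, 0), speckle_jitter = 0)
}

augment_one <- function(img, policy) {
  s <- nrow(img)
  # random resized crop
  sc <- stats::runif(1, policy$crop_scale[1], policy$crop_scale[2])
  cs <- max(8L, round(s * sc))
  if (cs < s) {
    ou <- sample.int(s - cs + 1L, 1L)
    ov <- sample.int(s - cs + 1L, 1L)
    img <- resize_image(img[ou:(ou + cs - 1L), ov:(ov + cs - 1L)], s)
  }
  if (stats::runif(1) < policy$flip_prob) img <- img[, ncol(img):1]
  if (policy$brightness > 0)
    img <- img + stats::runif(1, -policy$brightness, policy$brightness)
  if (policy$contrast > 0) {
    m <- mean(img)
    img <- (img - m) * (1 + stats::runif(1, -policy$contrast, policy$contrast)) + m
  }
  if (policy$blur_sigma[2] > 0) {
    sg <- stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2])
    if (sg > 0.05) img <- blur_image(img, sg)
  }
  if (policy$speckle_jitter > 0)
    img <- img * (1 + policy$speckle_jitter * stats::rnorm(length(img)))
  out_frac <- mean(img < 0 | img > 1)
  if (out_frac > 0.6)
    warning(sprintf("augmentation clipped %.0f%% of pixels", 100 * out_frac),
            call. = FALSE)
  clamp01(img)
}

#' Generate two augmented views of a batch
#'
#' Applies two independently sampled transform draws to every image.
#' Deterministic given `(seed, batch order)`.
#'
#' @param batch Image array `(H, W, N)` in `[0, 1]`.
#' @param policy An [augmentation_policy()].
#' @param seed RNG seed.
#' @return `list(X1, X2)` of arrays shaped like `batch`.
#' @export
make_views <- function(batch, policy = augmentation_policy(), seed = 1L) {
  stopifnot(min(batch) >= 0, max(batch) <= 1)
  withr::with_seed(as.integer(seed), {
    N <- dim(batch)[3]
    one_view <- function() {
      out <- batch
      for (i in seq_len(N)) out[, , i] <- augment_one(batch[, , i], policy)
      out
    }
    list(X1 = one_view(), X2 = one_view())
  })
}
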