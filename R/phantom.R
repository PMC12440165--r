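# Synthetic B-mode gallbladder phantoms.
#
# The generator emulates the statistical structure a classifier must cope
# with in B-mode ultrasound, not the acoustics: a smooth tissue background
# carrying multiplicative speckle, a dark (anechoic) elliptical gallbladder
# lumen with an echogenic wall, and class-dependent lesions — benign: a
# compact bright focus with a sharp smooth margin; malignant: a larger
# mid-echogenic mass with an irregular (harmonically perturbed) margin,
# heterogeneous internal texture and a disrupted wall segment. Each synthetic
# patient owns one anatomy (and one class) shared, with small per-image
# perturbations, by all of that patient's images — mirroring how patient-level
# grouping works in real cohorts.

default_lesion_params <- function() {
  list(benign = list(radius = c(0.11, 0.17), brightness = c(0.42, 0.55),
                     irregularity = c(0.00, 0.04)),
       malignant = list(radius = c(0.18, 0.28), brightness = c(0.26, 0.38),
                        irregularity = c(0.25, 0.40),
                        texture = c(0.25, 0.38), wall_break = c(1.0, 1.8)))
}

#' Phantom dataset configuration
#'
#' Defaults emulate the class balance of a real gallbladder ultrasound cohort
#' (34.4% normal, 44.5% benign, 21.1% malignant) with several images per
#' patient and one label per patient.
#'
#' @param image_size Side length in pixels.
#' @param n_patients Number of synthetic patients.
#' @param images_per_patient `(min, max)` images drawn uniformly per patient.
#' @param class_proportions Length-3 probabilities (normal, benign,
#'   malignant) summing to 1.
#' @param speckle_scale Multiplicative speckle contrast (0 disables speckle).
#' @param lesion_params Per-class morphology ranges; see
#'   `default_lesion_params` in the source for the fields.
#' @param seed RNG seed; all outputs are pure functions of (config, seed).
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_patients = 60L,
                           images_per_patient = c(2L, 4L),
                           class_proportions = c(0.344, 0.445, 0.211),
                           speckle_scale = 0.30,
                           lesion_params = default_lesion_params(),
                           seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("phantom_config: class_proportions must sum to 1")
  stopifnot(images_per_patient[1] >= 1,
            images_per_patient[2] >= images_per_patient[1])
  structure(list(image_size = as.integer(image_size),
                 n_patients = as.integer(n_patients),
                 images_per_patient = as.integer(images_per_patient),
                 class_proportions = class_proportions,
                 speckle_scale = speckle_scale,
                 lesion_params = lesion_params, seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_classes <- c("normal", "benign", "malignant")

runifr <- function(r) stats::runif(1, r[1], r[2])

# One synthetic patient's anatomy; consumed by render_phantom.
sample_patient_params <- function(label, lesion_params = default_lesion_params()) {
  pp <- list(label = label,
             center = c(0.5 + stats::runif(1, -0.06, 0.06),
                        0.47 + stats::runif(1, -0.06, 0.06)),
             semi_a = stats::runif(1, 0.20, 0.27),
             semi_b = stats::runif(1, 0.12, 0.17),
             angle = stats::runif(1, -0.5, 0.5),
             wall = stats::runif(1, 0.025, 0.045),
             tissue_base = stats::runif(1, 0.50, 0.62),
             bg_freq = stats::runif(2, 1.5, 4),
             bg_phase = stats::runif(2, 0, 2 * pi))
  if (label == "benign") {
    lp <- lesion_params$benign
    pp$lesion <- list(radius = runifr(lp$radius),
                      brightness = runifr(lp$brightness),
                      irregularity = runifr(lp$irregularity),
                      theta = stats::runif(1, 0, 2 * pi))
  } else if (label == "malignant") {
    lp <- lesion_params$malignant
    pp$lesion <- list(radius = runifr(lp$radius),
                      brightness = runifr(lp$brightness),
                      irregularity = runifr(lp$irregularity),
                      texture = runifr(lp$texture),
                      wall_break = runifr(lp$wall_break),
                      theta = stats::runif(1, 0, 2 * pi),
                      harmonics = stats::runif(4, 0, 1),
                      phases = stats::runif(4, 0, 2 * pi))
  }
  pp
}

#' Render one synthetic B-mode phantom
#'
#' Deterministic given `(label, patient_params, seed)`. See the module
#' comment for the image model.
#'
#' @param label One of `"normal"`, `"benign"`, `"malignant"`; must match the
#'   patient's class.
#' @param patient_params Anatomy list from the generator (shared across a
#'   patient's images).
#' @param seed Per-image seed controlling speckle and small perturbations.
#' @param image_size Side length in pixels.
#' @param speckle_scale Multiplicative speckle contrast.
#' @return `image_size x image_size` matrix in `[0, 1]`.
#' @export
render_phantom <- function(label, patient_params, seed, image_size = 64L,
                           speckle_scale = 0.35) {
  if (!label %in% phantom_classes) stop("unknown label: ", label)
  pp <- patient_params
  s <- image_size
  withr::with_seed(as.integer(seed), {
    u <- matrix(rep(seq(0, 1, length.out = s), s), s, s)            # row coord
    v <- t(u)                                                       # col coord
    # per-image probe jitter: slight shift of the whole anatomy
    jit <- stats::runif(2, -0.015, 0.015)
    cu <- pp$center[1] + jit[1]; cv <- pp$center[2] + jit[2]
    # smooth tissue background
    bg <- pp$tissue_base +
      0.05 * cos(2 * pi * pp$bg_freq[1] * u + pp$bg_phase[1]) +
      0.05 * cos(2 * pi * pp$bg_freq[2] * v + pp$bg_phase[2])
    # ellipse coordinates (rotated)
    du <- u - cu; dv <- v - cv
    ru <- cos(pp$angle) * du + sin(pp$angle) * dv
    rv <- -sin(pp$angle) * du + cos(pp$angle) * dv
    q <- sqrt((ru / pp$semi_a)^2 + (rv / pp$semi_b)^2)              # 1 on the wall
    phi <- atan2(rv, ru)
    Timg <- bg
    Timg[q < 1] <- Timg[q < 1] * 0.15                               # anechoic lumen
    wall_gain <- 0.35 * exp(-((q - 1) / pp$wall)^2)                 # echogenic wall
    if (label == "malignant") {
      # suppress the wall over an angular sector (wall disruption)
      brk <- abs(((phi - pp$lesion$theta + pi) %% (2 * pi)) - pi) <
        pp$lesion$wall_break / 2
      wall_gain[brk] <- wall_gain[brk] * 0.15
    }
    Timg <- Timg + wall_gain
    if (label != "normal") {
      le <- pp$lesion
      # lesion center sits inside the lumen toward angle theta
      lc_u <- cu + 0.55 * pp$semi_a * cos(pp$angle) * cos(le$theta) -
        0.55 * pp$semi_b * sin(pp$angle) * sin(le$theta)
      lc_v <- cv + 0.55 * pp$semi_a * sin(pp$angle) * cos(le$theta) +
        0.55 * pp$semi_b * cos(pp$angle) * sin(le$theta)
      ld <- sqrt((u - lc_u)^2 + (v - lc_v)^2)
      lphi <- atan2(v - lc_v, u - lc_u)
      rad <- le$radius
      if (label == "malignant") {
        mod <- rep(0, length(lphi))
        for (k in seq_along(pp$lesion$harmonics))
          mod <- mod + pp$lesion$harmonics[k] * cos((k + 2) * lphi + pp$lesion$phases[k])
        rad <- le$radius * (1 + le$irregularity * mod / sum(pp$lesion$harmonics))
      }
      inside <- ld < rad
      if (label == "benign") {
        Timg[inside] <- pmax(Timg[inside], pp$tissue_base + le$brightness)
      } else {
        tex <- blur_image(matrix(stats::rnorm(s * s), s, s), 1.2)
        tex <- tex / stats::sd(tex)
        Timg[inside] <- pp$tissue_base * 0.25 + le$brightness +
          le$texture * tex[inside]
      }
    }
    # multiplicative speckle: smoothed exponential field, unit mean
    if (speckle_scale > 0) {
      sp <- blur_image(matrix(stats::rexp(s * s), s, s), 0.8)
      sp <- sp / mean(sp)
      Timg <- Timg * (1 + speckle_scale * (sp - 1))
    }
    clamp01(Timg)
  })
}

#' Generate a phantom dataset
#'
#' Draws patient classes from `class_proportions`, one anatomy per patient,
#' and renders each patient's images. When `dir` is given, PNG files and a
#' `manifest.csv` (columns `image_path,patient_id,label`) are written there;
#' the images are always returned in memory as well.
#'
#' @param cfg A [phantom_config()].
#' @param dir Optional output directory (created if missing).
#' @return List with `manifest` (data frame) and `images` (`(H, W, N)`
#'   array ordered as the manifest).
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  res <- withr::with_seed(cfg$seed, {
    cls <- sample(phantom_classes, cfg$n_patients, replace = TRUE,
                  prob = cfg$class_proportions)
    rows <- list(); imgs <- list()
    for (p in seq_len(cfg$n_patients)) {
      pp <- sample_patient_params(cls[p], cfg$lesion_params)
      rng <- cfg$images_per_patient
      n_img <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
      for (k in seq_len(n_img)) {
        img_seed <- as.integer((as.numeric(cfg$seed) * 100003 + p * 131 + k) %%
                                 2147483629)
        img <- render_phantom(cls[p], pp, img_seed, cfg$image_size,
                              cfg$speckle_scale)
        i <- length(rows) + 1L
        rows[[i]] <- data.frame(
          image_path = sprintf("p%03d_i%02d.png", p, k),
          patient_id = sprintf("P%03d", p),
          label = cls[p], stringsAsFactors = FALSE)
        imgs[[i]] <- img
      }
    }
    list(manifest = do.call(rbind, rows),
         images = array(unlist(imgs, use.names = FALSE),
                        dim = c(cfg$image_size, cfg$image_size, length(imgs))))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(res$manifest)))
      save_image(res$images[, , i], file.path(dir, res$manifest$image_path[i]))
    # the CSV keeps paths relative to its own directory (portable);
    # read_manifest resolves them
    utils::write.csv(res$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    res$manifest$image_path <- file.path(dir, res$manifest$image_path)
  }
  res
}

#' Corrupt an image with spatially correlated Gaussian noise
#'
#' Adds zero-mean Gaussian noise whose standard deviation is `level` times
#' the dynamic range (images live in `[0, 1]`, so simply `level`). The noise
#' field is smoothed by a Gaussian kernel of `kernel_sigma` pixels and then
#' rescaled back to the target standard deviation, yielding spatially
#' correlated noise; the output is clamped to `[0, 1]`.
#'
#' @param image Matrix in `[0, 1]`.
#' @param level Noise standard deviation as a fraction of the dynamic range.
#' @param kernel_sigma Spatial smoothing sigma of the noise field, pixels.
#' @param seed RNG seed for the noise draw.
#' @return Corrupted image, same shape.
#' @export
corrupt_noise <- function(image, level, kernel_sigma = 5, seed = 1L) {
  if (level < 0) stop("corrupt_noise: level must be nonnegative")
  if (level == 0) return(image)
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(length(image)), nrow(image), ncol(image))
    noise <- blur_image(noise, kernel_sigma)
    noise <- noise / stats::sd(noise) * level
    clamp01(image + noise)
  })
}

#' Margin/texture irregularity score
#'
#' A deliberately simple hand-coded discriminant used to validate the
#' generator: the compactness (boundary length over square-rooted area) of
#' the dark lumen region plus the local roughness of mid-intensity pixels.
#' Malignant phantoms — irregular margins, heterogeneous internal texture,
#' broken walls — score high; normal and benign phantoms score low.
#'
#' @param image Matrix in `[0, 1]`.
#' @return Scalar score (higher = more malignant-looking).
#' @export
margin_irregularity_score <- function(image) {
  sm <- blur_image(image, 1)
  mask <- sm < 0.25
  area <- sum(mask)
  if (area < 9) return(1e3)   # lumen mostly destroyed: maximally suspicious
  inner <- mask
  inner[-1, ] <- inner[-1, ] & mask[-nrow(mask), ]
  inner[-nrow(mask), ] <- inner[-nrow(mask), ] & mask[-1, ]
  inner[, -1] <- inner[, -1] & mask[, -ncol(mask)]
  inner[, -ncol(mask)] <- inner[, -ncol(mask)] & mask[, -1]
  boundary <- sum(mask & !inner)
  compact <- boundary / sqrt(area)
  gx <- sm[-1, ] - sm[-nrow(sm), ]
  mid <- (sm[-1, ] + sm[-nrow(sm), ]) / 2
  rough <- mean(abs(gx)[mid > 0.25 & mid < 0.55])
  compact + 25 * rough
}
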