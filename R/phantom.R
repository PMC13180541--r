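# Seeded synthetic MRI-like phantoms with low-contrast lesions.
#
# Four classes mirror the composition of public brain-tumour MRI
# collections: no_tumor, meningioma, glioma, pituitary. Lesion signatures
# follow the radiological caricature of each type: pituitary adenomas are
# small regular ellipses near the lower-centre (sellar region); meningiomas
# are well-defined ellipses attached to the brain rim (dural attachment);
# gliomas are irregular star-convex blobs with blurred boundaries and
# internal heterogeneity. "No tumor" scans carry one whole-image box so that
# four-class mAP is computable (the class is evaluated like any other).

PHANTOM_CLASSES <- c("no_tumor", "meningioma", "glioma", "pituitary")

#' Configuration for the phantom generator
#'
#' @param image_size square image side in pixels (>= 16)
#' @param class_weights probability per class over
#'   (no_tumor, meningioma, glioma, pituitary); must be non-negative and sum
#'   to 1. The default is proportional to the class counts
#'   (880, 1738, 1408, 1705) of the public brain-tumour MRI collection the
#'   generator emulates.
#' @param contrast_range lesion-vs-background intensity offset range, as a
#'   fraction of the dynamic range
#' @param boundary_blur_range Gaussian sigma range (pixels) smoothing the
#'   lesion mask edge
#' @param heterogeneity within-lesion texture amplitude (relative to the
#'   lesion contrast)
#' @param noise_sigma Rician noise scale (magnitude-MRI noise model)
#' @param seed integer seed; the same (config, seed) pair always produces a
#'   byte-identical dataset
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(image_size = 96L,
                           class_weights = c(880, 1738, 1408, 1705) / 5731,
                           contrast_range = c(0.15, 0.35),
                           boundary_blur_range = c(0.5, 2.5),
                           heterogeneity = 0.3,
                           noise_sigma = 0.05,
                           seed = 0L) {
  if (image_size < 16) stop("image_size must be >= 16, got ", image_size)
  if (length(class_weights) != 4L || any(class_weights < 0)) {
    stop("class_weights must be 4 non-negative values")
  }
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("class_weights must sum to 1 (got ", sum(class_weights), ")")
  }
  if (contrast_range[1] < 0) stop("contrast_range low must be >= 0")
  if (boundary_blur_range[1] < 0) stop("boundary_blur_range low must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 class_weights = class_weights,
                 contrast_range = contrast_range,
                 boundary_blur_range = boundary_blur_range,
                 heterogeneity = heterogeneity,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed),
                 class_names = PHANTOM_CLASSES),
            class = "phantom_config")
}

.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

# Smooth random field in [-1, 1]-ish range (blurred white noise, rescaled).
.smooth_noise <- function(S, sigma) {
  z <- matrix(stats::rnorm(S * S), S, S)
  z <- .gblur(z, sigma)
  z / max(stats::sd(z), 1e-8)
}

#' Generate one synthetic phantom
#'
#' Draws the class from `config$class_weights`, renders the brain-like
#' background and the class-specific lesion, and derives the tight bounding
#' box from the noiseless soft lesion mask (pixels with mask >= 0.5), never
#' from the final noisy image.
#'
#' @param config a [phantom_config()]
#' @param rng_state optional integer; when given, seeds the RNG before
#'   generation (otherwise the current RNG stream is consumed)
#' @return object of class `image_sample`: `image` (S x S matrix in [0, 1],
#'   row = y), `boxes` (n x 5 matrix: class_id, cx, cy, w, h normalized),
#'   `class_id`, and `meta` (contrast, blur, lesion area, the soft lesion
#'   mask and the brain-background mask)
#' @export
generate_phantom <- function(config, rng_state = NULL) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  if (!is.null(rng_state)) set.seed(rng_state)
  S <- config$image_size
  yy <- matrix(rep(seq_len(S) - 0.5, S), S, S) / S        # row coord (y)
  xx <- matrix(rep(seq_len(S) - 0.5, each = S), S, S) / S # col coord (x)

  cls <- sample.int(4L, 1L, prob = config$class_weights) - 1L

  # brain-like elliptical background with smooth tissue texture
  a <- 0.36 + stats::runif(1, -0.02, 0.02)
  b <- 0.42 + stats::runif(1, -0.02, 0.02)
  brain <- (((xx - 0.5) / a)^2 + ((yy - 0.5) / b)^2) <= 1
  tex <- .smooth_noise(S, S / 12)
  img <- ifelse(brain, 0.45 + 0.06 * tex, 0.02)

  contrast <- stats::runif(1, config$contrast_range[1], config$contrast_range[2])
  blur_lo <- config$boundary_blur_range[1]
  blur_hi <- config$boundary_blur_range[2]
  blur_mid <- (blur_lo + blur_hi) / 2

  mask <- NULL
  blur <- 0
  het <- 0
  if (cls == 1L) {           # meningioma: sharp ellipse touching the rim
    blur <- stats::runif(1, blur_lo, blur_mid)
    het <- config$heterogeneity * 0.5
    th <- stats::runif(1, 0, 2 * pi)
    r1 <- stats::runif(1, 0.08, 0.13)
    cx <- 0.5 + (a - 0.8 * r1) * cos(th)
    cy <- 0.5 + (b - 0.8 * r1) * sin(th)
    r2 <- r1 * stats::runif(1, 0.75, 1)
    rot <- stats::runif(1, 0, pi)
    xr <- (xx - cx) * cos(rot) + (yy - cy) * sin(rot)
    yr <- -(xx - cx) * sin(rot) + (yy - cy) * cos(rot)
    mask <- ((xr / r1)^2 + (yr / r2)^2) <= 1
  } else if (cls == 2L) {    # glioma: irregular star-convex blob
    blur <- stats::runif(1, blur_mid, blur_hi)
    het <- config$heterogeneity
    cx <- 0.5 + stats::runif(1, -0.45, 0.45) * a
    cy <- 0.5 + stats::runif(1, -0.45, 0.45) * b
    r0 <- stats::runif(1, 0.09, 0.16)
    K <- 10L
    pert <- stats::runif(K, -0.35, 0.35)
    # periodic linear interpolation of the radius profile
    phi_k <- seq(0, 2 * pi, length.out = K + 1L)[-(K + 1L)]
    rad_k <- r0 * (1 + pert)
    ang <- atan2(yy - cy, xx - cx) %% (2 * pi)
    seg <- pmin(floor(ang / (2 * pi / K)) + 1L, K)
    t <- (ang - phi_k[seg]) / (2 * pi / K)
    nxt <- ifelse(seg == K, 1L, seg + 1L)
    rloc <- rad_k[seg] * (1 - t) + rad_k[nxt] * t
    rho <- sqrt((xx - cx)^2 + (yy - cy)^2)
    mask <- rho <= rloc
  } else if (cls == 3L) {    # pituitary: small regular sellar ellipse
    blur <- stats::runif(1, blur_lo, blur_mid)
    het <- config$heterogeneity * 0.5
    cx <- 0.5 + stats::runif(1, -0.03, 0.03)
    cy <- 0.62 + stats::runif(1, -0.03, 0.03)
    r1 <- stats::runif(1, 0.05, 0.08)
    r2 <- r1 * stats::runif(1, 0.85, 1)
    mask <- (((xx - cx) / r1)^2 + ((yy - cy) / r2)^2) <= 1
  }

  boxes <- matrix(numeric(0), 0L, 5L)
  meta <- list(contrast = if (cls == 0L) 0 else contrast, blur = blur,
               lesion_area = 0, softmask = NULL, brain = brain)
  if (cls == 0L) {
    boxes <- matrix(c(0, 0.5, 0.5, 1, 1), 1L, 5L)
  } else {
    soft <- .gblur(mask + 0, blur)
    # normalise to peak 1 and plateau the interior: the lesion core sits at
    # the full requested contrast while the rim stays smoothly blurred
    soft <- pmin(soft / (0.9 * max(soft)), 1)
    # lesion contribution: contrast times soft mask, with internal texture
    ltex <- .smooth_noise(S, 2)
    img <- img + contrast * soft * (1 + het * ltex)
    core <- soft >= 0.5
    meta$lesion_area <- sum(core)
    meta$softmask <- soft
    rows <- which(rowSums(core) > 0)   # y extent
    cols <- which(colSums(core) > 0)   # x extent
    x1 <- (min(cols) - 1) / S; x2 <- max(cols) / S
    y1 <- (min(rows) - 1) / S; y2 <- max(rows) / S
    boxes <- matrix(c(cls, (x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1),
                    1L, 5L)
  }
  colnames(boxes) <- c("class_id", "cx", "cy", "w", "h")

  if (config$noise_sigma > 0) {
    n1 <- matrix(stats::rnorm(S * S, sd = config$noise_sigma), S, S)
    n2 <- matrix(stats::rnorm(S * S, sd = config$noise_sigma), S, S)
    img <- sqrt((img + n1)^2 + n2^2)  # Rician magnitude
  }
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = img, boxes = boxes, class_id = cls, meta = meta),
            class = "image_sample")
}

#' Generate a seeded phantom dataset
#'
#' @param config a [phantom_config()]
#' @param n number of samples
#' @return list of `image_sample` objects; attribute `counts` holds the
#'   per-class sample counts
#' @export
generate_dataset <- function(config, n) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  set.seed(config$seed)
  samples <- vector("list", n)
  for (i in seq_len(n)) samples[[i]] <- generate_phantom(config)
  counts <- tabulate(vapply(samples, function(s) s$class_id, 0L) + 1L, 4L)
  names(counts) <- PHANTOM_CLASSES
  attr(samples, "counts") <- counts
  samples
}
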