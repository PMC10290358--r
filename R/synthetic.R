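# Procedural reed/water textures and composite scenes with exact ground-truth
# masks. Textures are statistical caricatures: reed is an anisotropic,
# vertically striated green-brown pattern; water is a smooth low-frequency
# blue-grey field. The two classes differ in mean colour and in the
# axis-wise variance ratio (see axis_variance_ratio) by documented margins.

reed_palette  <- c(0.42, 0.50, 0.24) # green-brown
water_palette <- c(0.33, 0.42, 0.55) # blue-grey

# Evaluate thunk with a seeded, restored RNG state so generators are
# deterministic without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# Bilinear upsample of a coarse matrix to H x W.
bilinear_upsample <- function(m, height, width) {
  gr <- nrow(m); gc <- ncol(m)
  u <- (seq_len(height) - 0.5) / height * (gr - 1) + 1
  v <- (seq_len(width) - 0.5) / width * (gc - 1) + 1
  i0 <- pmin(floor(u), gr - 1); fi <- u - i0
  j0 <- pmin(floor(v), gc - 1); fj <- v - j0
  a <- m[i0, j0, drop = FALSE]; b <- m[i0 + 1, j0, drop = FALSE]
  cc <- m[i0, j0 + 1, drop = FALSE]; d <- m[i0 + 1, j0 + 1, drop = FALSE]
  fi <- matrix(fi, height, width); fj <- matrix(fj, height, width,
                                                byrow = TRUE)
  a * (1 - fi) * (1 - fj) + b * fi * (1 - fj) + cc * (1 - fi) * fj +
    d * fi * fj
}

#' Generate a pure-class texture
#'
#' `kind = "reed"` produces a vertically striated anisotropic pattern
#' (dominant spatial frequency across columns, green-brown palette) plus
#' seeded noise; `kind = "water"` a low-frequency smooth field (blue-grey
#' palette) plus seeded noise. Outputs are deterministic given `seed`.
#' Margins held by construction (and asserted in the test suite): the reed
#' texture's [axis_variance_ratio()] exceeds 1.5, the water texture's lies in
#' `[0.67, 1.5]`, and the class mean colours differ strongly in the
#' green-minus-blue direction.
#'
#' @param kind `"reed"` or `"water"`.
#' @param height,width Dimensions in pixels, each at least 8.
#' @param seed Integer RNG seed.
#' @param stripe_period Reed striation period in pixels.
#' @param noise_amplitude Standard deviation of the per-pixel noise.
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
make_texture <- function(kind = c("reed", "water"), height, width, seed,
                         stripe_period = 5, noise_amplitude = 0.03) {
  kind <- match.arg(kind)
  stopifnot(height >= 8, width >= 8)
  with_seed(seed, {
    if (kind == "reed") {
      base <- reed_palette
      # vertical stems: sinusoid across columns with slow per-row phase drift
      phase <- cumsum(stats::rnorm(height, 0, 0.015))
      stripe <- sin(2 * pi * (outer(phase, seq_len(width) / stripe_period,
                                    "+")))
      # per-stem brightness so stems are individually visible
      stem <- stats::rnorm(ceiling(width / stripe_period) + 1, 0, 0.05)
      stem_cols <- stem[ceiling(seq_len(width) / stripe_period)]
      chan_w <- c(0.8, 1.0, 0.4) # striation mostly in R and G
      img <- array(0, c(height, width, 3))
      for (ch in 1:3) {
        img[, , ch] <- base[ch] + 0.12 * chan_w[ch] * stripe +
          matrix(stem_cols, height, width, byrow = TRUE) +
          stats::rnorm(height * width, 0, noise_amplitude)
      }
    } else {
      base <- water_palette
      g <- max(4L, round(min(height, width) / 16))
      img <- array(0, c(height, width, 3))
      for (ch in 1:3) {
        coarse <- matrix(stats::rnorm((g + 1)^2, 0, 0.05), g + 1, g + 1)
        img[, , ch] <- base[ch] + bilinear_upsample(coarse, height, width) +
          stats::rnorm(height * width, 0, noise_amplitude)
      }
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    img
  })
}

#' Anisotropy of a texture: x- vs y-direction increment variance
#'
#' The ratio of the mean squared luminance difference between horizontally
#' adjacent pixels (along x, i.e. across the stripe-normal axis for vertical
#' striation) to that between vertically adjacent pixels (along y). Vertically
#' striated textures give ratios well above 1; isotropic fields give ratios
#' near 1.
#'
#' @param image Array `H x W x C` or matrix.
#' @return Positive scalar.
#' @export
axis_variance_ratio <- function(image) {
  lum <- if (length(dim(image)) == 3L) {
    apply(image, c(1, 2), mean)
  } else {
    image
  }
  dx <- lum[, -1, drop = FALSE] - lum[, -ncol(lum), drop = FALSE]
  dy <- lum[-1, , drop = FALSE] - lum[-nrow(lum), , drop = FALSE]
  mean(dx^2) / mean(dy^2)
}

#' Scene specification for the synthetic generator
#'
#' @param height,width Scene dimensions in pixels.
#' @param target_coverage Desired reed fraction in `[0, 1]`; patches are
#'   placed until the mask is within 0.02 of this value.
#' @param n_patches Maximum number of reed patches to place.
#' @param stripe_period,noise_amplitude Texture parameters, see
#'   [make_texture()].
#' @param seed Integer RNG seed.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256, width = 256, target_coverage = 0.4,
                       n_patches = 64, stripe_period = 5,
                       noise_amplitude = 0.03, seed = 0) {
  stopifnot(target_coverage >= 0, target_coverage <= 1,
            height >= 8, width >= 8, n_patches >= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_coverage = target_coverage,
                 n_patches = as.integer(n_patches),
                 stripe_period = stripe_period,
                 noise_amplitude = noise_amplitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Binary mask of an axis-aligned ellipse/rectangle; a pixel belongs to the
# patch iff the patch covers the pixel centre.
patch_mask <- function(height, width, cy, cx, ry, rx, shape) {
  yy <- matrix(seq_len(height) - 0.5, height, width)
  xx <- matrix(seq_len(width) - 0.5, height, width, byrow = TRUE)
  if (shape == "ellipse") {
    ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
  } else {
    abs(yy - cy) <= ry & abs(xx - cx) <= rx
  }
}

#' Compose a synthetic scene with exact ground truth
#'
#' Places random elliptical/rectangular reed patches on a water background
#' until the mask's mean is within 0.02 of `target_coverage`, then renders
#' reed texture inside the mask and water texture outside. The recorded
#' `true_coverage` is the exact mean of the final mask.
#'
#' @param spec A [scene_spec()].
#' @return Object of class `ground_truth_scene`: list with `image`
#'   (`H x W x 3`), `mask` (binary `H x W` matrix, reed = 1) and
#'   `true_coverage`.
#' @export
compose_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  target <- spec$target_coverage
  mask <- with_seed(spec$seed + 1L, {
    m <- matrix(FALSE, h, w)
    if (target >= 1) {
      m[] <- TRUE
    } else if (target > 0) {
      placed <- 0L; attempts <- 0L
      npix <- h * w
      while (mean(m) < target - 0.02) {
        attempts <- attempts + 1L
        if (attempts > 40L * spec$n_patches || placed >= spec$n_patches)
          stop("target coverage ", target, " unreachable with n_patches = ",
               spec$n_patches, "; increase n_patches or patch size")
        remaining <- (target - mean(m)) * npix
        area <- max(16, remaining * stats::runif(1, 0.5, 1.0))
        rho <- exp(stats::runif(1, -0.6, 0.6))
        ry <- sqrt(area * rho / pi); rx <- sqrt(area / (rho * pi))
        cy <- stats::runif(1, 0, h); cx <- stats::runif(1, 0, w)
        shape <- if (stats::runif(1) < 0.7) "ellipse" else "rectangle"
        cand <- m | patch_mask(h, w, cy, cx, ry, rx, shape)
        if (mean(cand) <= target + 0.02) {
          m <- cand
          placed <- placed + 1L
        }
      }
    }
    m
  })
  reed <- make_texture("reed", h, w, seed = spec$seed + 2L,
                       stripe_period = spec$stripe_period,
                       noise_amplitude = spec$noise_amplitude)
  water <- make_texture("water", h, w, seed = spec$seed + 3L,
                        noise_amplitude = spec$noise_amplitude)
  m3 <- array(rep(mask, 3L), c(h, w, 3L))
  image <- ifelse(m3, reed, water)
  dim(image) <- c(h, w, 3L)
  structure(list(image = image, mask = matrix(as.integer(mask), h, w),
                 true_coverage = mean(mask), spec = spec),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene %dx%d px, true reed coverage %.4f\n",
              nrow(x$mask), ncol(x$mask), x$true_coverage))
  invisible(x)
}

#' Generate a pure-class training corpus
#'
#' Produces `n_per_class` all-reed and `n_per_class` all-water images,
#' emulating field photographs in which reed is 100 percent present and
#' photographs of areas not covered with reed. Deterministic given `seed`.
#'
#' @param n_per_class Images per class.
#' @param image_size Side of each square image in pixels.
#' @param seed Integer RNG seed.
#' @return List with elements `reed` and `non_reed`, each a list of
#'   `image_size x image_size x 3` arrays.
#' @export
make_training_corpus <- function(n_per_class = 20, image_size = 64,
                                 seed = 0) {
  stopifnot(n_per_class >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      2L * n_per_class))
  reed <- lapply(seq_len(n_per_class), function(i)
    make_texture("reed", image_size, image_size, seed = seeds[i]))
  non_reed <- lapply(seq_len(n_per_class), function(i)
    make_texture("water", image_size, image_size,
                 seed = seeds[n_per_class + i]))
  list(reed = reed, non_reed = non_reed)
}
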