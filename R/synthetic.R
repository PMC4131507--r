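# Deterministic synthetic scenes with exact ground truth.  The default scene
# is a two-region image in which the object/background intensity ranges
# overlap globally (a smooth background ramp) while the local contrast stays
# constant — the configuration on which global-prototype region models fail
# and locally fitted ones succeed.

#' Intensity-inhomogeneous ring-and-arch scene
#'
#' A 143 x 150 scene (by default) consisting of a ring and a detached
#' bottom arch drawn over a linear background ramp. The background intensity
#' runs from `ramp[2]` at the top row to `ramp[1]` at the bottom row, and
#' every object pixel is the local background plus `offset`: global intensity
#' ranges overlap (the dim bottom arch is darker than the bright top
#' background) but the local object/background contrast is `offset`
#' everywhere. The ground-truth mask is the exact geometry indicator before
#' any degradation.
#'
#' @param height,width scene size in pixels.
#' @param ramp background intensity range `c(bottom, top)`.
#' @param offset object intensity added over the local background; a warning
#'   is issued if `< 1` (no usable local contrast).
#' @param ring_center,ring_radii ring (annulus) center `(row, col)` and radii
#'   `c(inner, outer)` in pixels.
#' @param arch_radii the detached arch is a bottom arc of a second annulus
#'   concentric with the ring, with these radii.
#' @param arch_drop the arc spans rows at least this far below the ring
#'   center.
#' @return list with `image` (intensities in `[0, 255]`), `truth` (logical
#'   object mask), and `spec` (the resolved geometry parameters).
#' @examples
#' scn <- ramp_ring_scene()
#' range(scn$image[scn$truth] - scn$image[!scn$truth][1])
#' @export
ramp_ring_scene <- function(height = 143L, width = 150L,
                            ramp = c(20, 120), offset = 60,
                            ring_center = c(60, 75), ring_radii = c(9, 25),
                            arch_radii = c(33, 45), arch_drop = 14) {
  if (offset < 1) warning("object offset < 1 intensity unit: no usable local contrast")
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  # ramp[2] at the top row, ramp[1] at the bottom row
  bg <- ramp[2] - (ramp[2] - ramp[1]) * (rows - 1) / (height - 1)
  d <- sqrt((rows - ring_center[1])^2 + (cols - ring_center[2])^2)
  ring <- d >= ring_radii[1] & d <= ring_radii[2]
  arch <- d >= arch_radii[1] & d <= arch_radii[2] &
    rows >= ring_center[1] + arch_drop
  truth <- ring | arch
  img <- pmin(pmax(bg + offset * truth, 0), 255)
  list(image = img, truth = truth,
       spec = list(height = height, width = width, ramp = ramp,
                   offset = offset, ring_center = ring_center,
                   ring_radii = ring_radii, arch_radii = arch_radii,
                   arch_drop = arch_drop))
}

#' Add i.i.d. Gaussian noise to an image
#'
#' Zero-mean noise with standard deviation `sd`, clipped to `[0, 255]`
#' (clipping is part of the noise model). Reproducible via `seed`.
#'
#' @param image numeric intensity matrix.
#' @param sd noise standard deviation (intensity units), `>= 0`.
#' @param seed integer RNG seed.
#' @return degraded image.
#' @export
add_gaussian_noise <- function(image, sd = 10, seed = 1L) {
  check_gray_image(image)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (sd == 0) return(image)
  set.seed(seed)
  pmin(pmax(image + stats::rnorm(length(image), 0, sd), 0), 255)
}

#' Add salt-and-pepper noise to an image
#'
#' Corrupts exactly `round(fraction * n)` distinct pixels (sampled without
#' replacement), each set to 0 or 255 with equal probability.
#'
#' @param image numeric intensity matrix.
#' @param fraction fraction of pixels corrupted, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return degraded image.
#' @export
add_salt_pepper <- function(image, fraction = 0.02, seed = 1L) {
  check_gray_image(image)
  if (fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  k <- round(fraction * length(image))
  if (k == 0) return(image)
  set.seed(seed)
  idx <- sample.int(length(image), k)
  image[idx] <- sample(c(0, 255), k, replace = TRUE)
  image
}

#' Ring-and-arch scene with blurred boundaries
#'
#' The [ramp_ring_scene()] image convolved with a normalized Gaussian of
#' standard deviation `blur_sigma` (windows are renormalized at the image
#' border, so total intensity is preserved up to small border effects). The
#' ground truth stays the pre-blur geometry indicator.
#'
#' @param blur_sigma blur standard deviation in pixels, `> 0`.
#' @param ... passed to [ramp_ring_scene()].
#' @return list with `image`, `truth`, `spec`.
#' @export
blurred_scene <- function(blur_sigma = 2, ...) {
  if (blur_sigma <= 0) stop("`blur_sigma` must be positive", call. = FALSE)
  scn <- ramp_ring_scene(...)
  g <- kernel_weights(gauss_kernel(blur_sigma))
  ones <- matrix(1, nrow(scn$image), ncol(scn$image))
  scn$image <- conv2_same(scn$image, g) / conv2_same(ones, g)
  scn$spec$blur_sigma <- blur_sigma
  scn
}

#' The default four-scene evaluation suite
#'
#' Clean, blurred-boundary, Gaussian-noise and salt-and-pepper variants of the
#' ring-and-arch scene, with their shared exact ground truth. All randomness
#' flows through `seed`.
#'
#' @param seed integer RNG seed for the noisy variants.
#' @param gaussian_sd Gaussian noise standard deviation.
#' @param sp_fraction salt-and-pepper corruption fraction.
#' @param blur_sigma boundary blur standard deviation.
#' @return named list of scenes (`clean`, `blurred`, `gaussian`,
#'   `salt_pepper`), each with `image`, `truth`, `spec`.
#' @export
scene_suite <- function(seed = 1L, gaussian_sd = 10, sp_fraction = 0.02,
                        blur_sigma = 2) {
  clean <- ramp_ring_scene()
  blur <- blurred_scene(blur_sigma)
  gauss <- clean
  gauss$image <- add_gaussian_noise(clean$image, gaussian_sd, seed)
  gauss$spec$gaussian_sd <- gaussian_sd
  sp <- clean
  sp$image <- add_salt_pepper(clean$image, sp_fraction, seed + 1L)
  sp$spec$sp_fraction <- sp_fraction
  list(clean = clean, blurred = blur, gaussian = gauss, salt_pepper = sp)
}

#' Geometric seed membership map
#'
#' Builds the initial membership encoding of a rectangular or circular seed
#' contour: above 0.5 within the seed, below 0.5 elsewhere.
#'
#' The default is the two-level encoding (`inside` within the seed,
#' `outside` elsewhere). With `jitter = TRUE` each pixel instead draws a
#' random degree, uniform on `(0.5, inside]` within the seed and on
#' `[outside, 0.5)` elsewhere, which is useful for probing sensitivity of a
#' fit to the initial membership values.
#'
#' @param height,width grid size.
#' @param shape `"rectangle"` or `"circle"`.
#' @param rows,cols integer ranges of the rectangle; default spans roughly
#'   the central portion of the grid.
#' @param center,radius circle parameters (`(row, col)` and pixels).
#' @param inside,outside extreme membership values
#'   (`inside > 0.5 > outside`).
#' @param jitter randomize degrees within each side instead of the two-level
#'   encoding.
#' @param seed RNG seed for the jittered init.
#' @return numeric membership matrix.
#' @export
init_membership <- function(height, width, shape = c("rectangle", "circle"),
                            rows = NULL, cols = NULL,
                            center = NULL, radius = NULL,
                            inside = 0.8, outside = 0.2,
                            jitter = FALSE, seed = 1L) {
  shape <- match.arg(shape)
  if (inside <= 0.5 || outside >= 0.5)
    stop("seed requires `inside` > 0.5 and `outside` < 0.5", call. = FALSE)
  fg <- matrix(FALSE, height, width)
  if (shape == "rectangle") {
    if (is.null(rows)) rows <- round(0.28 * height):round(0.7 * height)
    if (is.null(cols)) cols <- round(0.35 * width):round(0.65 * width)
    fg[rows, cols] <- TRUE
  } else {
    if (is.null(center)) center <- c(round(height / 2), round(width / 2))
    if (is.null(radius)) radius <- round(min(height, width) / 4)
    r <- matrix(seq_len(height), height, width)
    c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
    fg[(r - center[1])^2 + (c_ - center[2])^2 <= radius^2] <- TRUE
  }
  if (jitter) {
    set.seed(seed)
    u <- matrix(stats::runif(height * width, outside, 0.5 - 1e-6),
                height, width)
    n_in <- sum(fg)
    u[fg] <- stats::runif(n_in, 0.5 + 1e-6, inside)
  } else {
    u <- matrix(outside, height, width)
    u[fg] <- inside
  }
  u
}
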