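# Truncated Gaussian kernel windows and the spatially varying prototype
# fields built with them.

#' Truncated Gaussian kernel window
#'
#' Weights `g(d) = 1/(2*pi*sigma) * exp(-d^2 / (2*sigma^2))` on the
#' `(2*radius+1) x (2*radius+1)` offset grid, `d` the Euclidean offset length
#' in pixels. The default truncation radius `ceiling(3*sigma)` captures
#' essentially all of the kernel mass. `normalize = "unit"` rescales so the
#' center weight is exactly 1 (the leading constant cancels wherever the
#' kernel enters a weighted mean; the unit-center convention makes the
#' incremental energy rule of [delta_f()] exact — see the package vignette).
#'
#' @param sigma kernel standard deviation in pixels, `> 0`.
#' @param radius truncation radius in pixels, `>= 1`.
#' @param normalize `"printed"` for the `1/(2*pi*sigma)` constant, `"unit"`
#'   for a center weight of 1.
#' @return numeric weight matrix of class `gauss_kernel` with attributes
#'   `sigma` and `radius`.
#' @examples
#' k <- gauss_kernel(1)
#' k[attr(k, "radius") + 1, attr(k, "radius") + 1]  # 1 / (2 * pi)
#' @export
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma),
                         normalize = c("printed", "unit")) {
  normalize <- match.arg(normalize)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a positive scalar", call. = FALSE)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    stop("`radius` must be an integer >= 1", call. = FALSE)
  off <- seq(-radius, radius)
  d2 <- outer(off^2, off^2, "+")
  g <- exp(-d2 / (2 * sigma^2))
  g <- if (normalize == "printed") g / (2 * pi * sigma) else g
  structure(g, class = "gauss_kernel", sigma = sigma, radius = radius,
            normalize = normalize)
}

# Strip kernel attributes for arithmetic.
kernel_weights <- function(kernel) {
  if (inherits(kernel, "gauss_kernel")) unclass(kernel) else kernel
}

#' Spatially varying local prototypes
#'
#' For every pixel, kernel-weighted fuzzy means of the intensities in its
#' window:
#' `c1(x) = sum_j u(j)^m g(x-j) I(j) / sum_j u(j)^m g(x-j)` and the analogue
#' with `(1-u)^m` for `c2`. The denominators `s1`, `s2` (the kernel-weighted
#' fuzzy mass of each region in the window) are returned as well; they feed
#' the incremental energy rule [delta_f()].
#'
#' At the image border, windows see the image reflected across the edge
#' (`border = "mirror"`, the default): for a locally linear intensity field
#' this leaves the window mean unbiased, whereas truncating the window shifts
#' it down the local gradient and fabricates spurious contrast along the
#' border. `border = "clip"` restricts the sums to in-image pixels (the
#' denominator is then the in-image kernel mass), which is the convention
#' under which a window covering the whole image reduces exactly to the
#' global prototypes. Where a denominator collapses below `floor` (a region
#' with no fuzzy mass in the window) the prototype falls back to the plain
#' kernel-weighted image mean.
#'
#' @param image numeric intensity matrix.
#' @param membership membership map, same shape.
#' @param kernel weight window from [gauss_kernel()] (any odd-sized numeric
#'   matrix of positive weights is accepted).
#' @param m fuzzy coefficient, `> 1`.
#' @param border `"mirror"` or `"clip"` window handling at the image edge.
#' @param floor positive lower bound protecting the denominators.
#' @return list of matrices `c1`, `c2`, `s1`, `s2`.
#' @export
local_prototypes <- function(image, membership, kernel, m = 2,
                             border = c("mirror", "clip"), floor = 1e-12) {
  border <- match.arg(border)
  check_gray_image(image)
  check_membership(membership, image)
  if (m <= 1) stop("fuzzy coefficient `m` must be > 1", call. = FALSE)
  g <- kernel_weights(kernel)
  wsum <- function(x) conv2_border(x, g, border)
  w1 <- membership^m
  w2 <- (1 - membership)^m
  s1 <- wsum(w1)
  s2 <- wsum(w2)
  n1 <- wsum(w1 * image)
  n2 <- wsum(w2 * image)
  deg1 <- s1 < floor
  deg2 <- s2 < floor
  c1 <- n1 / pmax(s1, floor)
  c2 <- n2 / pmax(s2, floor)
  if (any(deg1) || any(deg2)) {
    gm <- wsum(image) / wsum(matrix(1, nrow(image), ncol(image)))
    c1[deg1] <- gm[deg1]
    c2[deg2] <- gm[deg2]
  }
  list(c1 = c1, c2 = c2, s1 = pmax(s1, floor), s2 = pmax(s2, floor))
}

#' Robust pixel-noise estimate
#'
#' Median-absolute-deviation estimate of the standard deviation of additive
#' pixel noise: the image is smoothed with the (normalized) kernel window
#' and the MAD of the residual, scaled by 1.4826 for consistency at the
#' normal distribution, is returned. The median makes the estimate
#' insensitive to the minority of high-residual pixels at region boundaries
#' and to impulse (salt-and-pepper) outliers.
#'
#' @param image numeric intensity matrix.
#' @param kernel weight window from [gauss_kernel()].
#' @param border window border rule (see [local_prototypes()]).
#' @return non-negative scalar, in intensity units.
#' @export
estimate_noise_sd <- function(image, kernel = gauss_kernel(3),
                              border = c("mirror", "clip")) {
  border <- match.arg(border)
  check_gray_image(image)
  g <- kernel_weights(kernel)
  g <- g / sum(g)
  r <- image - conv2_border(image, g, border)
  stats::mad(r)
}
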