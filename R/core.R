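# Grid conventions: images and membership maps are plain numeric matrices,
# indexed (row, col); one pixel is one unit length.

check_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("`image` must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(image)))
    stop("`image` contains non-finite intensities", call. = FALSE)
  invisible(image)
}

check_membership <- function(u, image = NULL) {
  if (!is.matrix(u) || !is.numeric(u))
    stop("membership map must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(u)) || any(u < 0) || any(u > 1))
    stop("membership degrees must lie in [0, 1]", call. = FALSE)
  if (!is.null(image) && !identical(dim(u), dim(image)))
    stop("membership map and image must have the same dimensions", call. = FALSE)
  invisible(u)
}

#' Threshold a membership map into a binary object mask
#'
#' The contour is the 0.5 level of the membership map: pixels with membership
#' strictly above 0.5 belong to the object, pixels at or below 0.5 to the
#' background (ties go to the background so that the object is the strict
#' upper level set).
#'
#' @param membership numeric matrix with values in `[0, 1]`.
#' @return logical matrix, `TRUE` for object pixels.
#' @examples
#' u <- matrix(c(0.9, 0.4, 0.5, 0.51), 2, 2)
#' threshold_mask(u)
#' @export
threshold_mask <- function(membership) {
  check_membership(membership)
  membership > 0.5
}

# Zero-padded 2-D correlation via FFT: out[r, c] = sum_k k[i, j] *
# x[r + i - cr, c + j - cc], with x taken as 0 outside its support.  Used for
# all sliding-window sums (local prototypes, blurring, binary morphology
# counts); handles kernels larger than the image, which windowed filters in
# contributed packages refuse.
conv2_same <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2L == 0L || kc %% 2L == 0L)
    stop("kernel dimensions must be odd", call. = FALSE)
  # correlation = convolution with the flipped kernel
  k <- k[kr:1, kc:1, drop = FALSE]
  pr <- nr + kr - 1L
  pc <- nc + kc - 1L
  xp <- matrix(0, pr, pc); xp[seq_len(nr), seq_len(nc)] <- x
  kp <- matrix(0, pr, pc); kp[seq_len(kr), seq_len(kc)] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

# Reflect out-of-range indices back into 1..n (mirror without repeating the
# edge sample: 0 -> 2, n+1 -> n-1).
mirror_index <- function(t, n) {
  t <- ifelse(t < 1L, 2L - t, t)
  ifelse(t > n, 2L * n - t, t)
}

# Window sums with a border rule: "clip" treats outside as absent (zero
# padding), "mirror" reflects the image across its edges first.
conv2_border <- function(x, k, border = c("mirror", "clip")) {
  border <- match.arg(border)
  if (border == "clip") return(conv2_same(x, k))
  R <- (nrow(k) - 1L) %/% 2L
  C <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (R + 1L > nr || C + 1L > nc)
    stop("mirror border needs the kernel radius to be smaller than the image",
         call. = FALSE)
  ri <- mirror_index((1L - R):(nr + R), nr)
  ci <- mirror_index((1L - C):(nc + C), nc)
  full <- conv2_same(x[ri, ci, drop = FALSE], k)
  full[R + seq_len(nr), C + seq_len(nc), drop = FALSE]
}

# Structuring elements as 0/1 matrices.
se_square <- function(n = 3L) matrix(1, n, n)

se_disc <- function(radius) {
  off <- seq(-radius, radius)
  d2 <- outer(off^2, off^2, "+")
  (d2 <= radius^2) * 1
}

# Binary morphology on logical matrices.  The image is padded with background
# (0), so erosion removes foreground touching the border and dilation can
# grow across it.  Exact despite the FFT: window counts are integers and the
# numerical error is ~1e-9.
binary_erode <- function(mask, se) {
  cnt <- conv2_same(mask * 1, se)
  cnt > sum(se) - 0.5
}

# Erosion that treats out-of-image pixels as foreground: only boundaries
# that exist inside the image erode, so a mask filling the whole image has
# no boundary.  Used for contour extraction.
binary_erode_inside <- function(mask, se) {
  cnt <- conv2_same(mask * 1, se)
  avail <- conv2_same(matrix(1, nrow(mask), ncol(mask)), se)
  cnt > avail - 0.5
}

binary_dilate <- function(mask, se) {
  cnt <- conv2_same(mask * 1, se)
  cnt > 0.5
}
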