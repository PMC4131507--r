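# Global-prototype fuzzy active contour (FAC) baseline.
#
# The model minimizes, over membership map u and region prototypes c1, c2,
#
#   F(u, c1, c2) = lambda1 * sum u^m (I - c1)^2
#                + lambda2 * sum (1-u)^m (I - c2)^2
#
# by alternating the closed-form prototype update (fuzzy-weighted region
# means) with the closed-form per-pixel membership minimizer.  The curve-
# length regularizer of the full energy is omitted: it plays no role for the
# piecewise-smooth scenes this model targets and the minimization used here
# drops it.

#' Global fuzzy region prototypes
#'
#' Fuzzy-weighted mean intensities of the regions inside (`c1`) and outside
#' (`c2`) the evolving contour:
#' `c1 = sum(u^m I) / sum(u^m)`, `c2 = sum((1-u)^m I) / sum((1-u)^m)`.
#'
#' @param image numeric intensity matrix.
#' @param membership membership map in `[0, 1]`, same shape.
#' @param m fuzzy coefficient, `> 1`.
#' @return list with elements `c1` and `c2`.
#' @export
global_prototypes <- function(image, membership, m = 2) {
  check_gray_image(image)
  check_membership(membership, image)
  if (m <= 1) stop("fuzzy coefficient `m` must be > 1", call. = FALSE)
  w1 <- membership^m
  w2 <- (1 - membership)^m
  s1 <- sum(w1)
  s2 <- sum(w2)
  if (s1 == 0 || s2 == 0)
    stop("degenerate partition: one region has zero fuzzy mass", call. = FALSE)
  list(c1 = sum(w1 * image) / s1, c2 = sum(w2 * image) / s2)
}

#' Closed-form membership update
#'
#' For fixed prototypes the energy is minimized pixelwise by
#' `u = 1 / (1 + (lambda1 (I-c1)^2 / (lambda2 (I-c2)^2))^(1/(m-1)))`.
#' Degenerate distances follow the formula's limits: if the pixel intensity
#' equals both prototypes the update is 0.5; if it equals only `c1` (resp.
#' `c2`) the update is 1 (resp. 0).
#'
#' @param intensity pixel intensity (vectorized).
#' @param c1,c2 region prototypes (scalars or conformable arrays).
#' @param m fuzzy coefficient, `> 1`.
#' @param lambda1,lambda2 positive region weights.
#' @return membership degrees in `[0, 1]`, same shape as `intensity`.
#' @export
fac_membership <- function(intensity, c1, c2, m = 2, lambda1 = 1, lambda2 = 1) {
  if (m <= 1) stop("fuzzy coefficient `m` must be > 1", call. = FALSE)
  if (lambda1 <= 0 || lambda2 <= 0)
    stop("region weights must be positive", call. = FALSE)
  d1 <- lambda1 * (intensity - c1)^2
  d2 <- lambda2 * (intensity - c2)^2
  u <- 1 / (1 + (d1 / d2)^(1 / (m - 1)))
  u[d1 == 0 & d2 == 0] <- 0.5
  u[d1 == 0 & d2 > 0] <- 1
  u[d2 == 0 & d1 > 0] <- 0
  u
}

#' Fuzzy energy with global prototypes
#'
#' @inheritParams global_prototypes
#' @param prototypes list with `c1`, `c2` (as from [global_prototypes()]).
#' @param lambda1,lambda2 positive region weights.
#' @return non-negative scalar energy.
#' @export
fac_energy <- function(image, membership, prototypes, m = 2,
                       lambda1 = 1, lambda2 = 1) {
  check_gray_image(image)
  check_membership(membership, image)
  lambda1 * sum(membership^m * (image - prototypes$c1)^2) +
    lambda2 * sum((1 - membership)^m * (image - prototypes$c2)^2)
}

#' Morphological narrow band around the contour
#'
#' Crisps the membership map with a hard step at 0.5, extracts the inner
#' boundary of the object (the object minus its erosion by a 3x3 square) and
#' expands it by dilation with a disc of radius 5.  The erosion treats
#' out-of-image pixels as foreground, so only contours that exist inside the
#' image produce a boundary (a map that is object everywhere has none); the
#' dilation is clipped at the image edge.
#'
#' @param membership membership map in `[0, 1]`.
#' @param square side of the square erosion element (pixels).
#' @param radius radius of the disc dilation element (pixels).
#' @return logical band mask.
#' @export
morph_band <- function(membership, square = 3L, radius = 5L) {
  check_membership(membership)
  fg <- membership > 0.5
  boundary <- fg & !binary_erode_inside(fg, se_square(square))
  binary_dilate(boundary, se_disc(radius))
}

#' Fit the global-prototype fuzzy active contour (FAC)
#'
#' Alternates [global_prototypes()] with the full-image closed-form membership
#' update until the energy change drops below `epsilon` or `max_iters` sweeps
#' have run. Both half-steps are exact coordinate minimizations, so the energy
#' trace is non-increasing.
#'
#' @param image numeric intensity matrix (use [read_gray_image()] for files).
#' @param init initial partition: a logical/0-1 object mask, a membership
#'   matrix in `[0, 1]`, or `NULL` for the default centered rectangle seed
#'   (see [init_membership()]). Masks are encoded as membership `inside` /
#'   `outside`.
#' @param m fuzzy coefficient, `> 1`.
#' @param lambda1,lambda2 positive region weights.
#' @param epsilon absolute energy-change stopping tolerance.
#' @param relative if `TRUE` the stopping test uses the relative change
#'   `|F_t - F_{t-1}| / max(F_{t-1}, 1)`; the energy scales with image area,
#'   so this is useful on large images.
#' @param max_iters sweep cap.
#' @param inside,outside membership values encoding a mask/seed init.
#' @return an object of class `c("fac", "fuzzy_ac")`; see [lfac()] for the
#'   shared fields and methods.
#' @examples
#' scn <- ramp_ring_scene()
#' fit <- fac(scn$image)
#' p_mp(scn$truth, fit)   # global prototypes fail on the intensity ramp
#' @export
fac <- function(image, init = NULL, m = 2, lambda1 = 1, lambda2 = 1,
                epsilon = 1e-2, relative = FALSE, max_iters = 500L,
                inside = 0.8, outside = 0.2, seed = 1L) {
  check_gray_image(image)
  u <- resolve_init(init, dim(image), inside, outside, seed)
  cl <- match.call()

  energy <- numeric(0)
  f_prev <- Inf
  converged <- FALSE
  reason <- "max_iters"
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    cc <- global_prototypes(image, u, m)
    u <- fac_membership(image, cc$c1, cc$c2, m, lambda1, lambda2)
    f <- fac_energy(image, u, cc, m, lambda1, lambda2)
    energy <- c(energy, f)
    df <- abs(f - f_prev)
    if (relative) df <- df / max(abs(f_prev), 1)
    if (is.finite(f_prev) && df < epsilon) {
      converged <- TRUE
      reason <- "energy"
      break
    }
    f_prev <- f
  }

  structure(list(
    membership = u,
    mask = threshold_mask(u),
    prototypes = cc,
    energy = energy[length(energy)],
    energy_trace = energy,
    band_trace = rep(length(image), iter),
    accepted_trace = rep(NA_integer_, iter),
    updates = length(image) * iter,
    iterations = iter,
    converged = converged,
    reason = reason,
    params = list(model = "fac", m = m, lambda1 = lambda1, lambda2 = lambda2,
                  epsilon = epsilon, relative = relative,
                  max_iters = max_iters, inside = inside, outside = outside,
                  seed = seed),
    dim = dim(image),
    call = cl
  ), class = c("fac", "fuzzy_ac"))
}

# Turn the user-supplied init (mask, membership map, or NULL) into a valid
# membership map.
resolve_init <- function(init, dims, inside = 0.8, outside = 0.2,
                         seed = 1L) {
  if (is.null(init)) {
    u <- init_membership(dims[1], dims[2], inside = inside, outside = outside,
                         seed = seed)
  } else if (is.logical(init) || all(init %in% c(0, 1))) {
    if (!identical(dim(init), dims))
      stop("init mask and image must have the same dimensions", call. = FALSE)
    u <- matrix(outside, dims[1], dims[2])
    u[init > 0] <- inside
  } else {
    check_membership(init)
    if (!identical(dim(init), dims))
      stop("init membership and image must have the same dimensions",
           call. = FALSE)
    u <- init
  }
  if (all(u == 0.5))
    stop("degenerate initial partition: membership is 0.5 everywhere",
         call. = FALSE)
  u
}
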