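# Partition-based fuzzy active contour with local information (LFAC): the
# energy of the FAC model with the global prototypes replaced by the
# spatially varying local means of local_prototypes(), minimized by
# candidate-and-accept sweeps restricted to a narrow band around the contour.

#' Incremental energy change of a single-pixel membership update
#'
#' Signed change of the pixel's local energy contribution when its membership
#' moves from `u_o` to `u_n`, accounting for the shift the move induces in the
#' pixel's own prototypes:
#'
#' `dF = (u_n^m (s1 / (s1 + u_n^m - u_o^m))^2 - u_o^m) (I - c1)^2 +
#'       ((1-u_n)^m (s2 / (s2 + (1-u_n)^m - (1-u_o)^m))^2 - (1-u_o)^m) (I - c2)^2`
#'
#' With the unit-center-weight kernel convention (see [gauss_kernel()]), this
#' equals exactly the difference obtained by rebuilding `c1`, `c2`, `s1`, `s2`
#' from scratch with the new membership. All arguments are vectorized.
#'
#' @param u_o,u_n old and candidate membership degrees in `[0, 1]`.
#' @param intensity pixel intensity `I`.
#' @param c1,c2 local prototypes at the pixel.
#' @param s1,s2 local kernel-weighted fuzzy masses at the pixel (positive).
#' @param m fuzzy coefficient, `> 1`.
#' @return signed energy differences; `NA` where an updated denominator would
#'   not be positive (a degenerate update, which callers must reject).
#' @export
delta_f <- function(u_o, u_n, intensity, c1, c2, s1, s2, m = 2) {
  if (m <= 1) stop("fuzzy coefficient `m` must be > 1", call. = FALSE)
  a_o <- u_o^m
  a_n <- u_n^m
  b_o <- (1 - u_o)^m
  b_n <- (1 - u_n)^m
  d1 <- s1 + a_n - a_o
  d2 <- s2 + b_n - b_o
  out <- (a_n * (s1 / d1)^2 - a_o) * (intensity - c1)^2 +
         (b_n * (s2 / d2)^2 - b_o) * (intensity - c2)^2
  out[d1 <= 0 | d2 <= 0] <- NA_real_
  out
}

#' Fuzzy energy with spatially varying prototypes
#'
#' `F = sum u^m (I - c1(x))^2 + sum (1-u)^m (I - c2(x))^2`, with the local
#' prototype fields recomputed from the current membership over the full
#' domain.
#'
#' @inheritParams local_prototypes
#' @return non-negative scalar energy.
#' @export
lfac_energy <- function(image, membership, kernel, m = 2,
                        border = c("mirror", "clip")) {
  pf <- local_prototypes(image, membership, kernel, m, border)
  sum(membership^m * (image - pf$c1)^2) +
    sum((1 - membership)^m * (image - pf$c2)^2)
}

#' One candidate-and-accept sweep over a band
#'
#' For every band pixel, forms the closed-form candidate update (the
#' [fac_membership()] formula with the local prototypes of
#' [local_prototypes()] substituted, `lambda1 = lambda2 = 1`) and accepts it
#' only where the incremental energy change [delta_f()] is strictly negative.
#' Pixels outside the band are untouched.
#'
#' Two deterministic sweep disciplines are provided. `"batch"` (default)
#' evaluates all candidates against the sweep-start prototype fields and
#' applies the accepted ones at once, mirroring the two-phase structure of
#' the algorithm (prototypes for the whole region first, then the
#' accept/reject pass); with a uniform window covering the whole image it
#' reproduces one global-prototype ([fac()]) sweep exactly. `"sequential"`
#' visits band pixels in raster (row-major) order and recomputes the window
#' sums from the current state at every pixel, so each update sees its
#' already-updated neighbors (coordinate-descent style); the acceptance test
#' is then exact at the moment of each update, at the price of letting label
#' decisions cascade within a single sweep.
#'
#' @param image numeric intensity matrix.
#' @param membership sweep-start membership map.
#' @param kernel weight window; rescaled internally to unit center weight
#'   unless `center_weight = "printed"`.
#' @param band logical mask of updatable pixels (must contain at least one).
#' @param m fuzzy coefficient, `> 1`.
#' @param sweep pixel-update discipline, `"sequential"` or `"batch"`.
#' @param border window handling at the image edge (see
#'   [local_prototypes()]).
#' @param center_weight kernel convention for the masses `s1`, `s2`; `"unit"`
#'   makes the acceptance rule exact (default).
#' @param accept_tol minimum energy decrease for accepting a candidate (a
#'   candidate is accepted only if its energy change is below
#'   `-accept_tol`). The default 4 is the squared quantization scale of
#'   8-bit intensities: an update justified by less than ~2 gray levels of
#'   local contrast is indistinguishable from quantization error or from the
#'   one-sided window bias at image borders, and accepting such updates lets
#'   pseudo-evidence flip label regions. [lfac()] raises this automatically
#'   on noisy images. Set to a small positive value (e.g. 1e-9) to accept
#'   every strictly energy-decreasing update.
#' @return list: `membership` (updated map), `accepted` (count of accepted
#'   updates), `visited` (number of band pixels).
#' @export
lfac_step <- function(image, membership, kernel, band, m = 2,
                      sweep = c("batch", "sequential"),
                      border = c("mirror", "clip"),
                      center_weight = c("unit", "printed"),
                      accept_tol = 4) {
  sweep <- match.arg(sweep)
  border <- match.arg(border)
  center_weight <- match.arg(center_weight)
  check_membership(membership, image)
  if (!any(band)) stop("`band` is empty", call. = FALSE)
  g <- kernel_weights(kernel)
  if (center_weight == "unit") {
    ctr <- g[(nrow(g) + 1L) %/% 2L, (ncol(g) + 1L) %/% 2L]
    g <- g / ctr
  }
  mult <- self_weight(g, nrow(image), ncol(image), border)
  if (sweep == "batch") {
    pf <- local_prototypes(image, membership, g, m, border)
    u_n <- fac_membership(image, pf$c1, pf$c2, m)
    a_o <- membership^m;       a_n <- u_n^m
    b_o <- (1 - membership)^m; b_n <- (1 - u_n)^m
    den1 <- pf$s1 + mult * (a_n - a_o)
    den2 <- pf$s2 + mult * (b_n - b_o)
    df <- (a_n * (pf$s1 / den1)^2 - a_o) * (image - pf$c1)^2 +
          (b_n * (pf$s2 / den2)^2 - b_o) * (image - pf$c2)^2
    accept <- band & den1 > 0 & den2 > 0 & is.finite(df) & df < -accept_tol
    out <- membership
    out[accept] <- u_n[accept]
    return(list(membership = out, accepted = sum(accept), visited = sum(band)))
  }
  lfac_sweep_sequential(image, membership, g, band, m, border, mult,
                        accept_tol)
}

# Total kernel weight with which a pixel enters its own window: the center
# weight, plus — under the mirror border rule — the weight of its reflected
# copies that fall inside the window.  This is the effective increment that
# an update at the pixel applies to its own s1/s2, which the exact
# acceptance rule needs.
self_weight <- function(g, nr, nc, border) {
  R <- (nrow(g) - 1L) %/% 2L
  C <- (ncol(g) - 1L) %/% 2L
  gc <- g[R + 1L, C + 1L]
  if (border == "clip") return(matrix(gc, nr, nc))
  offs <- function(n, rad) lapply(seq_len(n), function(t) {
    v <- 0L
    a <- 2L - 2L * t          # copy reflected across the leading edge
    b <- 2L * n - 2L * t      # copy reflected across the trailing edge
    if (a != 0L && -a <= rad) v <- c(v, a)
    if (b != 0L && b <= rad) v <- c(v, b)
    v
  })
  ro <- offs(nr, R)
  co <- offs(nc, C)
  multi_c <- which(lengths(co) > 1L)
  M <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    grs <- colSums(g[ro[[r]] + R + 1L, , drop = FALSE])
    M[r, ] <- grs[C + 1L]
    for (cm in multi_c) M[r, cm] <- sum(grs[co[[cm]] + C + 1L])
  }
  M
}

# Raster-order Gauss-Seidel sweep: each band pixel recomputes its window
# sums from the current membership state (reflected or clipped at the
# border), so the acceptance test is exact at the moment of the update and
# already-updated neighbors are seen immediately.
lfac_sweep_sequential <- function(image, u, g, band, m, border, mult,
                                  accept_tol, floor = 1e-12) {
  nr <- nrow(u); nc <- ncol(u)
  R <- (nrow(g) - 1L) %/% 2L
  C <- (ncol(g) - 1L) %/% 2L
  mirror <- border == "mirror"
  if (mirror && (R + 1L > nr || C + 1L > nc))
    stop("mirror border needs the kernel radius to be smaller than the image",
         call. = FALSE)
  # reflected window indices, one column per pixel row/col
  ridx <- vapply(seq_len(nr), function(r) mirror_index((r - R):(r + R), nr),
                 integer(2L * R + 1L))
  cidx <- vapply(seq_len(nc), function(c_) mirror_index((c_ - C):(c_ + C), nc),
                 integer(2L * C + 1L))

  idx <- which(band)          # column-major; reorder to raster (row-major)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ord <- order(rr, cc)
  rr <- rr[ord]; cc <- cc[ord]
  accepted <- 0L

  for (k in seq_along(rr)) {
    r <- rr[k]; c_ <- cc[k]
    if (mirror) {
      uw <- u[ridx[, r], cidx[, c_]]
      iw <- image[ridx[, r], cidx[, c_]]
      gs <- g
    } else {
      rs <- max(1L, r - R):min(nr, r + R)
      cs <- max(1L, c_ - C):min(nc, c_ + C)
      uw <- u[rs, cs, drop = FALSE]
      iw <- image[rs, cs, drop = FALSE]
      gs <- g[rs - r + R + 1L, cs - c_ + C + 1L, drop = FALSE]
    }
    w1 <- uw^m * gs
    w2 <- (1 - uw)^m * gs
    s1 <- sum(w1); s2 <- sum(w2)
    if (s1 < floor || s2 < floor) next   # no fuzzy mass to fit against
    c1 <- sum(w1 * iw) / s1
    c2 <- sum(w2 * iw) / s2
    io <- image[r, c_]
    d1 <- (io - c1)^2
    d2 <- (io - c2)^2
    u_o <- u[r, c_]
    u_n <- if (d1 == 0 && d2 == 0) 0.5
           else if (d1 == 0) 1
           else if (d2 == 0) 0
           else 1 / (1 + (d1 / d2)^(1 / (m - 1)))
    if (u_n == u_o) next
    mu <- mult[r, c_]
    den1 <- s1 + mu * (u_n^m - u_o^m)
    den2 <- s2 + mu * ((1 - u_n)^m - (1 - u_o)^m)
    if (den1 <= 0 || den2 <= 0) next   # degenerate update: reject
    df <- (u_n^m * (s1 / den1)^2 - u_o^m) * d1 +
          ((1 - u_n)^m * (s2 / den2)^2 - (1 - u_o)^m) * d2
    if (!is.finite(df) || df >= -accept_tol) next
    u[r, c_] <- u_n
    accepted <- accepted + 1L
  }
  list(membership = u, accepted = accepted, visited = length(rr))
}

#' Fit the partition-based local fuzzy active contour (LFAC)
#'
#' Segments a single-channel image with smooth intensity inhomogeneity by
#' minimizing a fuzzy region energy whose prototypes are Gaussian-weighted
#' local means, updating per iteration only the pixels of a narrow band
#' around the current contour.
#'
#' The iteration is: (0) a full-domain warm-start sweep — a crisp seed makes
#' the shadowed-sets band empty, so one sweep over all pixels first produces
#' the continuous membership field the band detector needs; then repeatedly
#' (1) detect the band ([boundary_band()] by default), (2) run one
#' [lfac_step()] on it, (3) recompute the full-domain energy [lfac_energy()].
#' Fitting stops when the absolute energy change falls below `epsilon`, the
#' band comes back empty, a sweep accepts no update, or `max_iters` is hit.
#'
#' @inheritParams fac
#' @param sigma kernel standard deviation in pixels.
#' @param kernel_radius kernel truncation radius in pixels.
#' @param alpha_step grid step of the shadowed-sets threshold search.
#' @param band update-region detector: `"shadowed"` (adaptive, default — the
#'   shadowed-sets region [boundary_band()] united with the contour margin
#'   of [morph_band()], which recruits adjacent still-crisp pixels),
#'   `"morphological"` (the fixed-shape contour band of [morph_band()]
#'   alone), or `"none"` (update the full domain every sweep).
#' @param sweep pixel-update discipline passed to [lfac_step()].
#' @param border window border rule (see [local_prototypes()]).
#' @param center_weight kernel convention passed to [lfac_step()].
#' @param accept_tol minimum energy decrease per accepted update. The
#'   default `NULL` adapts it to the image:
#'   `max(4, 2 * estimate_noise_sd(image)^2)` — the 8-bit quantization floor
#'   (see [lfac_step()]), raised on noisy images so that updates explainable
#'   by pixel noise alone (energy gain of order `0.2 * noise^2` for a
#'   membership move across `[0, 1]`) are rejected and the evolution stays
#'   driven by structure, not noise.
#' @param seed RNG seed used only when the initial partition is generated or
#'   encoded with random degrees (see [init_membership()]).
#' @return an object of class `c("lfac", "fuzzy_ac")`: a list with
#'   `membership`, `mask` (strict 0.5 level set), `energy`, `energy_trace`,
#'   `band_trace` (band size per iteration), `accepted_trace`, `updates`
#'   (total pixels visited), `iterations`, `converged`, `reason`, `params`,
#'   `dim`, `call`. Methods: `print`, `summary`, `plot`, `fitted` (membership
#'   map), `predict` (mask or membership).
#' @examples
#' scn <- ramp_ring_scene()
#' fit <- lfac(scn$image)
#' fit
#' p_mp(scn$truth, fit)
#' @export
lfac <- function(image, init = NULL, m = 2, sigma = 3,
                 kernel_radius = ceiling(3 * sigma),
                 epsilon = 1e-2, relative = FALSE, max_iters = 500L,
                 alpha_step = 0.001,
                 band = c("shadowed", "morphological", "none"),
                 sweep = c("batch", "sequential"),
                 border = c("mirror", "clip"),
                 inside = 0.8, outside = 0.2,
                 center_weight = c("unit", "printed"),
                 accept_tol = NULL, seed = 1L) {
  band <- match.arg(band)
  sweep <- match.arg(sweep)
  border <- match.arg(border)
  center_weight <- match.arg(center_weight)
  check_gray_image(image)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  u <- resolve_init(init, dim(image), inside, outside, seed)
  cl <- match.call()
  kernel <- gauss_kernel(sigma, kernel_radius)
  if (is.null(accept_tol))
    accept_tol <- max(4, 2 * estimate_noise_sd(image, kernel, border)^2)
  full <- matrix(TRUE, nrow(image), ncol(image))
  npix <- length(image)

  energy <- numeric(0)
  band_sizes <- integer(0)
  accepted <- integer(0)
  updates <- 0L
  converged <- FALSE
  reason <- "max_iters"

  # Warm start: one sweep over the full domain.  A two-level init makes the
  # shadowed-sets band empty (the strict inequalities exclude the extreme
  # atoms); one full sweep produces the continuous membership values near
  # every intensity structure that the threshold search needs, while pixels
  # in unstructured neighborhoods see no energy gain and keep their seed
  # label (which anchors the object/background roles of the two prototypes).
  st <- lfac_step(image, u, kernel, full, m, sweep, border, center_weight,
                  accept_tol)
  u <- st$membership
  f_prev <- lfac_energy(image, u, kernel, m, border)
  energy <- f_prev
  band_sizes <- npix
  accepted <- st$accepted
  updates <- st$visited
  iter <- 1L

  while (iter < max_iters) {
    # The adaptive update region.  Shadow regions (strict inequalities)
    # cannot contain pixels still sitting at the extreme membership levels,
    # so on their own they cannot recruit fresh territory for the contour;
    # the union with the morphological contour margin keeps the evolution
    # able to claim adjacent crisp pixels while the shadow part adapts to
    # (and shrinks with) the remaining uncertainty.
    ra <- switch(band,
      shadowed = boundary_band(u, alpha_step) | morph_band(u),
      morphological = morph_band(u),
      none = full)
    if (!any(ra)) {
      converged <- TRUE
      reason <- "band_empty"
      break
    }
    iter <- iter + 1L
    st <- lfac_step(image, u, kernel, ra, m, sweep, border, center_weight,
                    accept_tol)
    u <- st$membership
    f <- lfac_energy(image, u, kernel, m, border)
    energy <- c(energy, f)
    band_sizes <- c(band_sizes, st$visited)
    accepted <- c(accepted, st$accepted)
    updates <- updates + st$visited
    if (st$accepted == 0L) {
      converged <- TRUE
      reason <- "no_updates"
      break
    }
    df <- abs(f - f_prev)
    if (relative) df <- df / max(abs(f_prev), 1)
    if (df < epsilon) {
      converged <- TRUE
      reason <- "energy"
      break
    }
    f_prev <- f
  }

  structure(list(
    membership = u,
    mask = threshold_mask(u),
    energy = energy[length(energy)],
    energy_trace = energy,
    band_trace = band_sizes,
    accepted_trace = accepted,
    updates = updates,
    iterations = iter,
    converged = converged,
    reason = reason,
    params = list(model = "lfac", m = m, sigma = sigma,
                  kernel_radius = kernel_radius, epsilon = epsilon,
                  relative = relative, max_iters = max_iters,
                  alpha_step = alpha_step, band = band, sweep = sweep,
                  border = border, inside = inside, outside = outside,
                  center_weight = center_weight, accept_tol = accept_tol,
                  seed = seed),
    dim = dim(image),
    call = cl
  ), class = c("lfac", "fuzzy_ac"))
}
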