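# Brute-force reference implementations used as independent oracles.
# All of them are direct loop transcriptions of the defining sums, written
# without reference to the package internals they check.

# reflect an index into 1..n (no edge repeat)
refl <- function(t, n) {
  t <- ifelse(t < 1, 2 - t, t)
  ifelse(t > n, 2 * n - t, t)
}

bf_global_prototypes <- function(image, u, m) {
  n1 <- d1 <- n2 <- d2 <- 0
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    n1 <- n1 + u[r, c]^m * image[r, c];       d1 <- d1 + u[r, c]^m
    n2 <- n2 + (1 - u[r, c])^m * image[r, c]; d2 <- d2 + (1 - u[r, c])^m
  }
  list(c1 = n1 / d1, c2 = n2 / d2)
}

# window sums at one pixel; border "clip" drops out-of-image offsets,
# "mirror" reflects them
bf_window <- function(image, u, g, m, r, c, border = "clip") {
  R <- (nrow(g) - 1) / 2
  C <- (ncol(g) - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  s1 <- s2 <- n1 <- n2 <- 0
  for (i in -R:R) for (j in -C:C) {
    ri <- r + i; ci <- c + j
    if (border == "clip") {
      if (ri < 1 || ri > nr || ci < 1 || ci > nc) next
    } else {
      ri <- refl(ri, nr); ci <- refl(ci, nc)
    }
    w <- g[i + R + 1, j + C + 1]
    s1 <- s1 + u[ri, ci]^m * w
    n1 <- n1 + u[ri, ci]^m * w * image[ri, ci]
    s2 <- s2 + (1 - u[ri, ci])^m * w
    n2 <- n2 + (1 - u[ri, ci])^m * w * image[ri, ci]
  }
  list(c1 = n1 / s1, c2 = n2 / s2, s1 = s1, s2 = s2)
}

bf_local_prototypes <- function(image, u, g, m, border = "clip") {
  c1 <- c2 <- s1 <- s2 <- matrix(0, nrow(image), ncol(image))
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    w <- bf_window(image, u, g, m, r, c, border)
    c1[r, c] <- w$c1; c2[r, c] <- w$c2; s1[r, c] <- w$s1; s2[r, c] <- w$s2
  }
  list(c1 = c1, c2 = c2, s1 = s1, s2 = s2)
}

bf_lfac_energy <- function(image, u, g, m, border = "clip") {
  f <- 0
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    w <- bf_window(image, u, g, m, r, c, border)
    f <- f + u[r, c]^m * (image[r, c] - w$c1)^2 +
      (1 - u[r, c])^m * (image[r, c] - w$c2)^2
  }
  f
}

# the pixel's local energy contribution with everything rebuilt from scratch
bf_local_contribution <- function(image, u, g, m, r, c, border = "clip") {
  w <- bf_window(image, u, g, m, r, c, border)
  u[r, c]^m * (image[r, c] - w$c1)^2 +
    (1 - u[r, c])^m * (image[r, c] - w$c2)^2
}

# shadowed-sets balance objective, direct three-term loop
bf_v <- function(values, alpha) {
  umax <- max(values)
  psi1 <- 0; psi2 <- 0; psi3 <- 0
  for (v in values) {
    if (v <= alpha) psi1 <- psi1 + v
    if (v >= umax - alpha) psi2 <- psi2 + (umax - v)
    if (v > alpha && v < umax - alpha) psi3 <- psi3 + 1
  }
  abs(psi1 + psi2 - psi3)
}

# pad: value assumed outside the image (FALSE = background padding,
# TRUE = out-of-image counts as foreground)
bf_erode <- function(mask, se, pad = FALSE) {
  R <- (nrow(se) - 1) / 2; C <- (ncol(se) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    keep <- TRUE
    for (i in -R:R) for (j in -C:C) {
      if (se[i + R + 1, j + C + 1] == 0) next
      ri <- r + i; ci <- c + j
      v <- if (ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask))
        mask[ri, ci] else pad
      if (!v) keep <- FALSE
    }
    out[r, c] <- keep
  }
  out
}

bf_dilate <- function(mask, se) {
  R <- (nrow(se) - 1) / 2; C <- (ncol(se) - 1) / 2
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    hit <- FALSE
    for (i in -R:R) for (j in -C:C) {
      if (se[i + R + 1, j + C + 1] == 0) next
      ri <- r + i; ci <- c + j
      if (ri >= 1 && ri <= nrow(mask) && ci >= 1 && ci <= ncol(mask) &&
          mask[ri, ci]) hit <- TRUE
    }
    out[r, c] <- hit
  }
  out
}

# small random instance shared by several tests
random_field <- function(nr, nc, seed, lo = 0, hi = 255) {
  set.seed(seed)
  list(image = matrix(runif(nr * nc, lo, hi), nr, nc),
       u = matrix(runif(nr * nc, 0.02, 0.98), nr, nc))
}
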