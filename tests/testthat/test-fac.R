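test_that("global prototypes are fuzzy-weighted region means", {
  u <- matrix(runif(9, 0.1, 0.9), 3, 3)
  expect_equal(global_prototypes(matrix(50, 3, 3), u)$c1, 50)
  expect_equal(global_prototypes(matrix(50, 3, 3), u)$c2, 50)

  # indicator membership reduces c1 to the unweighted mean over the region
  img <- matrix(1:12, 3, 4)
  ind <- matrix(0, 3, 4); ind[1:2, 1:2] <- 1
  expect_equal(global_prototypes(img, ind, m = 3)$c1, mean(img[1:2, 1:2]))

  set.seed(21)
  f <- random_field(3, 3, 21)
  got <- global_prototypes(f$image, f$u, m = 2)
  ref <- bf_global_prototypes(f$image, f$u, m = 2)
  expect_equal(got$c1, ref$c1, tolerance = 1e-10)
  expect_equal(got$c2, ref$c2, tolerance = 1e-10)
})

test_that("global prototypes reject a degenerate partition", {
  expect_error(global_prototypes(matrix(1, 2, 2), matrix(0, 2, 2)),
               "degenerate")
  expect_error(global_prototypes(matrix(1, 2, 2), matrix(1, 2, 2)),
               "degenerate")
})

test_that("membership update handles its closed forms and limits", {
  expect_equal(fac_membership(5, c1 = 5, c2 = 20), 1)
  expect_equal(fac_membership(20, c1 = 5, c2 = 20), 0)
  expect_equal(fac_membership(10, c1 = 5, c2 = 15), 0.5)
  expect_equal(fac_membership(7, c1 = 7, c2 = 7), 0.5)
  # ratio (5-0)^2/(5-20)^2 = 1/9 at m = 2 gives 1/(1 + 1/9) = 0.9
  expect_equal(fac_membership(5, c1 = 0, c2 = 20, m = 2), 0.9)
})

test_that("membership update minimizes the per-pixel energy", {
  grid <- seq(0, 1, by = 0.001)
  set.seed(31)
  for (i in 1:25) {
    I <- runif(1, 0, 255); c1 <- runif(1, 0, 255); c2 <- runif(1, 0, 255)
    m <- sample(c(1.5, 2, 3), 1)
    u_star <- fac_membership(I, c1, c2, m)
    e <- function(u) u^m * (I - c1)^2 + (1 - u)^m * (I - c2)^2
    expect_lte(e(u_star), min(e(grid)) + 1e-8)
  }
})

test_that("energy vanishes for a perfect crisp two-level fit", {
  img <- matrix(c(0, 0, 10, 10), 2, 2, byrow = TRUE)
  u <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  expect_equal(fac_energy(img, u, list(c1 = 10, c2 = 0)), 0)
  expect_equal(fac_energy(matrix(7, 2, 2), matrix(0.5, 2, 2),
                          list(c1 = 7, c2 = 7)), 0)
})

test_that("fac recovers a piecewise-constant two-level image exactly", {
  img <- matrix(40, 30, 30); img[8:22, 10:25] <- 200
  truth <- img > 100
  fit <- fac(img, init = init_membership(30, 30, rows = 10:20, cols = 12:20))
  expect_equal(p_mp(truth, fit), 0)
  expect_true(fit$converged)
  # deterministic: identical refit
  fit2 <- fac(img, init = init_membership(30, 30, rows = 10:20, cols = 12:20))
  expect_identical(fit$membership, fit2$membership)
})

test_that("fac energy trace never increases", {
  scn <- ramp_ring_scene(height = 60, width = 60, ring_center = c(30, 30),
                         ring_radii = c(5, 14), arch_radii = c(18, 25),
                         arch_drop = 8)
  fit <- fac(scn$image)
  expect_true(all(diff(fit$energy_trace) <= 1e-8))
})

test_that("morphological band matches direct morphology", {
  # map that is object everywhere has no contour, hence no band
  expect_false(any(morph_band(matrix(1, 21, 21))))

  # single foreground pixel: its boundary is itself, band is a radius-5 disc
  u2 <- matrix(0, 21, 21); u2[11, 11] <- 1
  off <- seq(-10, 10)
  disc <- outer(off^2, off^2, "+") <= 25
  expect_identical(morph_band(u2), disc)

  # half-plane: a straight strip around the 0.5 line, width set by B and R
  u3 <- matrix(0, 30, 30); u3[1:15, ] <- 1
  fg <- u3 > 0.5
  ref <- bf_dilate(fg & !bf_erode(fg, lfac:::se_square(3), pad = TRUE),
                   lfac:::se_disc(5))
  expect_identical(morph_band(u3), ref)
  # boundary is row 15; the radius-5 disc dilation spans rows 10..20
  expect_identical(sort(unique(which(morph_band(u3), arr.ind = TRUE)[, 1])),
                   10:20)
})
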