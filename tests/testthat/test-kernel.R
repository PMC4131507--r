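test_that("kernel weights follow the closed form", {
  k <- gauss_kernel(1)
  ctr <- k[attr(k, "radius") + 1, attr(k, "radius") + 1]
  expect_equal(ctr, 1 / (2 * pi))
  # one-offset ratio
  expect_equal(k[attr(k, "radius") + 1, attr(k, "radius") + 2] / ctr,
               exp(-1 / 2))
  k2 <- gauss_kernel(2.5, radius = 4)
  expect_equal(k2[5, 6] / k2[5, 5], exp(-1 / (2 * 2.5^2)))
  # symmetric under reflection, maximal at center, strictly positive
  w2 <- matrix(as.numeric(k2), 9, 9)
  expect_equal(w2, w2[9:1, 9:1])
  expect_true(all(w2 > 0))
  expect_equal(which.max(w2), 41L)  # center of the 9 x 9 window
  expect_error(gauss_kernel(-1), "positive")
  expect_error(gauss_kernel(1, radius = 0), ">= 1")
})

test_that("local prototypes of a uniform image equal its level", {
  u <- matrix(runif(64, 0.1, 0.9), 8, 8)
  pf <- local_prototypes(matrix(42, 8, 8), u, gauss_kernel(1.5))
  expect_equal(pf$c1, matrix(42, 8, 8))
  expect_equal(pf$c2, matrix(42, 8, 8))
})

test_that("uniform full-image window reduces local to global prototypes", {
  f <- random_field(7, 7, 8)
  flat <- matrix(1, 15, 15)   # covers the whole image from every pixel
  pf <- local_prototypes(f$image, f$u, flat, m = 2, border = "clip")
  gl <- global_prototypes(f$image, f$u, m = 2)
  expect_equal(pf$c1, matrix(gl$c1, 7, 7), tolerance = 1e-10)
  expect_equal(pf$c2, matrix(gl$c2, 7, 7), tolerance = 1e-10)
})

test_that("prototype fields match the quadruple-loop oracle", {
  for (border in c("clip", "mirror")) {
    f <- random_field(7, 7, 42)
    g <- unclass(gauss_kernel(1.5, radius = 3))
    got <- local_prototypes(f$image, f$u, g, m = 2, border = border)
    ref <- bf_local_prototypes(f$image, f$u, g, m = 2, border = border)
    expect_equal(got$c1, ref$c1, tolerance = 1e-8)
    expect_equal(got$c2, ref$c2, tolerance = 1e-8)
    expect_equal(got$s1, ref$s1, tolerance = 1e-8)
    expect_equal(got$s2, ref$s2, tolerance = 1e-8)
  }
  # the larger instance the relative-accuracy contract is stated for
  f <- random_field(16, 16, 43)
  g <- unclass(gauss_kernel(2, radius = 5))
  got <- local_prototypes(f$image, f$u, g, m = 2, border = "clip")
  ref <- bf_local_prototypes(f$image, f$u, g, m = 2, border = "clip")
  expect_equal(got$c1, ref$c1, tolerance = 1e-8)
  expect_equal(got$c2, ref$c2, tolerance = 1e-8)
})

test_that("prototypes stay within the window intensity range", {
  f <- random_field(12, 12, 9)
  pf <- local_prototypes(f$image, f$u, gauss_kernel(1.5), m = 2)
  expect_true(all(pf$c1 >= min(f$image) - 1e-9 & pf$c1 <= max(f$image) + 1e-9))
  expect_true(all(pf$c2 >= min(f$image) - 1e-9 & pf$c2 <= max(f$image) + 1e-9))
})

test_that("prototype fields are translation equivariant away from borders", {
  f <- random_field(14, 14, 10)
  g <- unclass(gauss_kernel(1, radius = 2))
  sh <- function(m, dr, dc) m[c((1 + dr):14, 1:dr), c((1 + dc):14, 1:dc)]
  a <- local_prototypes(f$image, f$u, g, m = 2)
  b <- local_prototypes(sh(f$image, 3, 2), sh(f$u, 3, 2), g, m = 2)
  # compare on the interior of the shifted frame, where no window touched a
  # border in either computation
  rows <- 3:9; cols <- 3:9
  expect_equal(b$c1[rows, cols], sh(a$c1, 3, 2)[rows, cols], tolerance = 1e-8)
  expect_equal(b$c2[rows, cols], sh(a$c2, 3, 2)[rows, cols], tolerance = 1e-8)
})

test_that("a window with no fuzzy mass falls back to the kernel mean", {
  img <- matrix(runif(49, 0, 255), 7, 7)
  u <- matrix(0, 7, 7)   # region 1 empty everywhere
  g <- unclass(gauss_kernel(1, radius = 2))
  pf <- local_prototypes(img, u, g, m = 2)
  ref <- lfac:::conv2_border(img, g, "mirror") /
    lfac:::conv2_border(matrix(1, 7, 7), g, "mirror")
  expect_equal(pf$c1, ref, tolerance = 1e-10)
  expect_true(all(is.finite(pf$c1)))
})

test_that("noise estimate recovers the noise scale and ignores edges", {
  set.seed(77)
  img <- matrix(100, 80, 80) + matrix(rnorm(6400, 0, 10), 80, 80)
  s <- estimate_noise_sd(img)
  expect_gt(s, 7); expect_lt(s, 13)
  # a clean piecewise scene has (almost) no residual noise
  scn <- ramp_ring_scene()
  expect_lt(estimate_noise_sd(scn$image), 1)
})
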