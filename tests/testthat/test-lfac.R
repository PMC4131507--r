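test_that("local-prototype energy matches the brute-force oracle", {
  u <- matrix(runif(36), 6, 6)
  expect_equal(lfac_energy(matrix(9, 6, 6), u, gauss_kernel(1)), 0)

  f <- random_field(8, 8, 81)
  g <- unclass(gauss_kernel(1.5, radius = 3))
  for (border in c("clip", "mirror")) {
    expect_equal(lfac_energy(f$image, f$u, g, 2, border),
                 bf_lfac_energy(f$image, f$u, g, 2, border),
                 tolerance = 1e-8)
  }
})

test_that("a sweep at a fixed point accepts nothing", {
  # membership already optimal for a crisp two-level image with matched
  # prototypes: candidates equal the current values
  img <- matrix(60, 10, 10); img[4:7, 4:7] <- 200
  u <- (img > 100) * 1
  u[u == 1] <- 0.999; u[u == 0] <- 0.001   # keep fuzzy masses positive
  st <- lfac_step(img, u, gauss_kernel(1.5), matrix(TRUE, 10, 10))
  expect_equal(st$accepted, 0)
  expect_identical(st$membership, u)
})

test_that("a pixel matching c1 is pulled to full membership", {
  # surrounding bright object mass makes c1 equal the pixel intensity
  img <- matrix(200, 9, 9); img[9, ] <- 20
  u <- matrix(0.9, 9, 9); u[9, ] <- 0.1
  u[5, 5] <- 0.2                      # misassigned object pixel
  st <- lfac_step(img, u, gauss_kernel(1.5), matrix(TRUE, 9, 9))
  expect_gt(st$membership[5, 5], 0.99)
})

test_that("sweeps are deterministic", {
  f <- random_field(12, 12, 90)
  band <- matrix(TRUE, 12, 12)
  for (sw in c("batch", "sequential")) {
    a <- lfac_step(f$image, f$u, gauss_kernel(1.5), band, sweep = sw)
    b <- lfac_step(f$image, f$u, gauss_kernel(1.5), band, sweep = sw)
    expect_identical(a, b)
  }
})

test_that("global uniform window reduces one sweep to one fac sweep", {
  f <- random_field(10, 10, 91)
  flat <- matrix(1, 21, 21)
  st <- lfac_step(f$image, f$u, flat, matrix(TRUE, 10, 10), m = 2,
                  sweep = "batch", border = "clip", accept_tol = 1e-12)
  gl <- global_prototypes(f$image, f$u, 2)
  ref <- fac_membership(f$image, gl$c1, gl$c2, 2)
  expect_equal(st$membership, ref, tolerance = 1e-8)
})

test_that("lfac segments the inhomogeneous scene exactly", {
  scn <- ramp_ring_scene()
  fit <- lfac(scn$image)
  expect_s3_class(fit, c("lfac", "fuzzy_ac"))
  expect_equal(p_mp(scn$truth, fit), 0)
  expect_true(fit$converged)
  # deterministic refit
  fit2 <- lfac(scn$image)
  expect_identical(fit$membership, fit2$membership)
  # result invariants
  expect_identical(fit$mask, threshold_mask(fit$membership))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
})

test_that("the adaptive band shrinks as the contour settles", {
  scn <- ramp_ring_scene()
  fit <- lfac(scn$image)
  expect_lt(tail(fit$band_trace, 1), fit$band_trace[2])
})

test_that("an uninformative initial partition is rejected", {
  scn <- ramp_ring_scene(height = 40, width = 40, ring_center = c(20, 20),
                         ring_radii = c(4, 10), arch_radii = c(13, 17),
                         arch_drop = 6)
  expect_error(lfac(scn$image, init = matrix(0.5, 40, 40)), "degenerate")
})

test_that("fit methods expose the segmentation", {
  scn <- ramp_ring_scene(height = 50, width = 50, ring_center = c(22, 25),
                         ring_radii = c(4, 11), arch_radii = c(15, 21),
                         arch_drop = 7)
  fit <- lfac(scn$image, init = init_membership(50, 50, rows = 12:38,
                                                cols = 12:38))
  expect_identical(fitted(fit), fit$membership)
  expect_identical(predict(fit), fit$mask)
  expect_identical(predict(fit, type = "membership"), fit$membership)
  expect_output(print(fit), "LFAC fit")
  expect_output(print(summary(fit)), "Parameters")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, image = scn$image))
})
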