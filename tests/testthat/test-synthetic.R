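test_that("the ramp-ring scene has the advertised structure", {
  scn <- ramp_ring_scene()
  expect_equal(dim(scn$image), c(143L, 150L))
  # constant local contrast: every object pixel is its background plus offset
  rows <- matrix(seq_len(143), 143, 150)
  bg <- 120 - 100 * (rows - 1) / 142
  expect_equal(scn$image[scn$truth] - bg[scn$truth],
               rep(60, sum(scn$truth)))
  expect_equal(scn$image[!scn$truth], bg[!scn$truth])
  # global ranges overlap: the dimmest object pixel is darker than the
  # brightest background pixel
  expect_lt(min(scn$image[scn$truth]), max(scn$image[!scn$truth]))
  expect_true(all(scn$image >= 0 & scn$image <= 255))
  # deterministic construction
  expect_identical(ramp_ring_scene(), scn)
  # zero offset: no signal, but the truth mask is still returned
  expect_warning(z <- ramp_ring_scene(offset = 0), "contrast")
  expect_identical(z$truth, scn$truth)
})

test_that("gaussian noise is centered, seeded, and clipped", {
  scn <- ramp_ring_scene()
  expect_identical(add_gaussian_noise(scn$image, sd = 0), scn$image)
  noisy <- add_gaussian_noise(scn$image, sd = 10, seed = 4)
  expect_identical(add_gaussian_noise(scn$image, sd = 10, seed = 4), noisy)
  d <- noisy - scn$image
  n <- length(d)
  expect_lt(abs(mean(d)), 3 * 10 / sqrt(n))   # CLT bound on the sample mean
  expect_true(all(noisy >= 0 & noisy <= 255))
})

test_that("salt-and-pepper noise corrupts an exact pixel count", {
  scn <- ramp_ring_scene()
  expect_identical(add_salt_pepper(scn$image, fraction = 0), scn$image)
  sp <- add_salt_pepper(scn$image, fraction = 0.02, seed = 9)
  expect_identical(add_salt_pepper(scn$image, fraction = 0.02, seed = 9), sp)
  changed <- sum(sp != scn$image)
  expect_equal(changed, round(0.02 * length(scn$image)))
  expect_true(all(sp[sp != scn$image] %in% c(0, 255)))
  all_sp <- add_salt_pepper(scn$image, fraction = 1, seed = 9)
  expect_true(all(all_sp %in% c(0, 255)))
})

test_that("boundary blur preserves intensity mass and the truth mask", {
  scn <- blurred_scene(blur_sigma = 2)
  clean <- ramp_ring_scene()
  expect_identical(scn$truth, clean$truth)
  expect_lt(abs(sum(scn$image) - sum(clean$image)) / sum(clean$image), 0.01)
  # vanishing blur approaches the clean scene
  tiny <- blurred_scene(blur_sigma = 0.2)
  expect_lt(max(abs(tiny$image - clean$image)), 0.1)
  expect_error(blurred_scene(blur_sigma = 0), "positive")
})

test_that("the scene suite is reproducible and complete", {
  a <- scene_suite(seed = 3)
  b <- scene_suite(seed = 3)
  expect_identical(a, b)
  expect_named(a, c("clean", "blurred", "gaussian", "salt_pepper"))
  for (s in a) expect_identical(dim(s$image), dim(s$truth))
})

test_that("seed membership maps encode the contour correctly", {
  u <- init_membership(30, 40, rows = 5:10, cols = 6:12)
  expect_equal(sort(unique(as.vector(u))), c(0.2, 0.8))
  expect_true(all(u[5:10, 6:12] == 0.8))
  circ <- init_membership(30, 30, shape = "circle", center = c(15, 15),
                          radius = 6)
  expect_true(circ[15, 15] > 0.5 && circ[1, 1] < 0.5)
  jit <- init_membership(30, 30, jitter = TRUE, seed = 2)
  expect_identical(init_membership(30, 30, jitter = TRUE, seed = 2), jit)
  expect_true(all((jit > 0.5) == (init_membership(30, 30) > 0.5)))
  expect_error(init_membership(10, 10, inside = 0.4), "> 0.5")
})
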