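test_that("difference of Gaussians rejects DC and matches direct convolution", {
  expect_error(dog_highpass(matrix(1, 8, 8), 2, 1),
               class = "ripplepond_bad_param")

  # constant image: response numerically zero everywhere
  fm <- dog_highpass(matrix(0.7, 40, 40))
  expect_lt(max(abs(fm)), 1e-6)

  # unit impulse: positive centre, negative surround annulus
  imp <- matrix(0, 31, 31)
  imp[16, 16] <- 1
  fi <- dog_highpass(imp)
  expect_gt(fi[16, 16], 0)
  expect_lt(fi[16, 12], 0)
  expect_lt(fi[12, 16], 0)

  # direct 2D convolution oracle on a random image, reflective boundaries
  set.seed(4)
  img <- matrix(runif(18 * 18), 18, 18)
  expect_equal(unclass(dog_highpass(img, 1, 2))[7:12, 7:12],
               dog_bruteforce(img, 1, 2)[7:12, 7:12],
               tolerance = 1e-12, ignore_attr = TRUE)

  # near-zero total response over a large constant region
  expect_lt(abs(sum(dog_highpass(matrix(0.5, 200, 200)))), 1e-3)
})

test_that("difference of Gaussians is linear", {
  set.seed(9)
  a <- matrix(runif(30 * 30), 30, 30)
  b <- matrix(runif(30 * 30), 30, 30)
  lhs <- dog_highpass(2 * a + 0.5 * b)
  rhs <- 2 * dog_highpass(a) + 0.5 * dog_highpass(b)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("radial Gabor orientation follows position angle", {
  set.seed(2)
  img <- matrix(runif(41 * 41), 41, 41)
  p <- gabor_params(alpha = 0.3, wavelength = 6, envelope_sigma = 2)

  # on the +x axis the position angle is 0, so the response equals a
  # Cartesian Gabor with theta = alpha
  rg <- radial_gabor(img, p)
  cg <- cartesian_gabor(img, p)
  expect_equal(rg[21, 35], cg[21, 35], tolerance = 1e-12)

  # on the +y axis with alpha = 0 the kernel points at pi/2, i.e. matches a
  # Cartesian Gabor with theta = pi/2
  p0 <- gabor_params(alpha = 0, wavelength = 6, envelope_sigma = 2)
  p90 <- gabor_params(alpha = pi / 2, wavelength = 6, envelope_sigma = 2)
  expect_equal(radial_gabor(img, p0)[8, 21], cartesian_gabor(img, p90)[8, 21],
               tolerance = 1e-12)

  expect_error(radial_gabor(matrix(0, 5, 5), gabor_params(envelope_sigma = 4)),
               class = "ripplepond_bad_param")
})

test_that("radial Gabor maps are rotation-equivariant; Cartesian maps are not", {
  set.seed(7)
  img <- matrix(runif(36 * 36), 36, 36)
  p <- gabor_params(alpha = 0.6, wavelength = 5, envelope_sigma = 2)

  for (k in 1:3) {                       # 90, 180, 270 degrees
    rot_in <- img
    for (i in seq_len(k)) rot_in <- rot90_ccw(rot_in)
    lhs <- radial_gabor(rot_in, p)
    rhs <- radial_gabor(img, p)
    for (i in seq_len(k)) rhs <- rot90_ccw(rhs)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }

  # negative control: the fixed-orientation map must fail the same test
  lhs <- cartesian_gabor(rot90_ccw(img), p)
  rhs <- rot90_ccw(cartesian_gabor(img, p))
  expect_gt(max(abs(lhs - rhs)), 0.1)
})

test_that("the Gabor bank rectifies and is consistent per channel", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  maps <- gabor_bank(img, alphas = c(0, pi / 4, pi / 2))
  expect_length(maps, 3L)
  expect_named(maps, c("radial_gabor_0", "radial_gabor_45", "radial_gabor_90"))
  expect_true(all(vapply(maps, min, numeric(1)) >= 0))

  one <- gabor_bank(img, alphas = pi / 4)
  expect_equal(unclass(one[[1]]),
               unclass(abs(radial_gabor(img, gabor_params(alpha = pi / 4)))),
               ignore_attr = TRUE)

  blank <- gabor_bank(matrix(0, 32, 32), alphas = c(0, pi / 2))
  expect_true(all(vapply(blank, max, numeric(1)) < 1e-12))

  expect_error(gabor_bank(img, alphas = numeric(0)),
               class = "ripplepond_bad_param")
})
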