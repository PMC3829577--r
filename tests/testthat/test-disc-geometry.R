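test_that("spec validation rejects degenerate discs", {
  expect_error(disc_spec(0, 4), class = "ripplepond_bad_spec")
  expect_error(disc_spec(8, 1), class = "ripplepond_bad_spec")
  expect_error(disc_spec(8, 4, trials = 0), class = "ripplepond_bad_spec")
})

test_that("disc layout has the prescribed counts, radii and symmetry", {
  lay <- build_disc(disc_spec(8, 4, trials = 50, seed = 7))
  expect_equal(nrow(lay), 8 * 3 + 1)

  lay5 <- build_disc(disc_spec(6, 5, trials = 10, seed = 1))
  expect_equal(attr(lay5, "ring_radius"), c(0, 0.5, sqrt(2) / 2, sqrt(3) / 2, 1),
               tolerance = 1e-7)

  # smallest possible disc: origin plus one neuron at radius 1
  tiny <- build_disc(disc_spec(1, 2, trials = 1, seed = 1))
  expect_equal(nrow(tiny), 2L)
  expect_equal(sqrt(tiny$x^2 + tiny$y^2), c(0, 1))

  # ring radii strictly increasing, outermost at 1, exactly arms per ring
  r <- attr(lay, "ring_radius")
  expect_true(all(diff(r) > 0))
  expect_equal(r[length(r)], 1)
  expect_equal(as.integer(table(lay$n)), c(1L, 8L, 8L, 8L))

  # consecutive angular spacing within each ring is exactly 2*pi/arms
  for (ring in 1:3) {
    ang <- sort(atan2(lay$y[lay$n == ring], lay$x[lay$n == ring]))
    expect_equal(diff(ang), rep(2 * pi / 8, 7), tolerance = 1e-9)
  }

  # the point set maps onto itself under rotation by 2*pi/arms
  a <- 2 * pi / 8
  rx <- lay$x * cos(a) - lay$y * sin(a)
  ry <- lay$x * sin(a) + lay$y * cos(a)
  mismatch <- vapply(seq_len(nrow(lay)), function(i) {
    min(sqrt((lay$x - rx[i])^2 + (lay$y - ry[i])^2))
  }, numeric(1))
  expect_lt(max(mismatch), 1e-9)
})

test_that("the layout is deterministic and leaves the caller's RNG alone", {
  a <- build_disc(disc_spec(12, 8, trials = 30, seed = 5))
  set.seed(999)
  before <- .Random.seed
  b <- build_disc(disc_spec(12, 8, trials = 30, seed = 5))
  expect_identical(before, .Random.seed)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "ring_offset"), attr(b, "ring_offset"))
})

test_that("optimized placement search matches the brute-force reference", {
  # trials = 1: the search degenerates to the raw random offsets
  ref <- build_disc_bruteforce(5, 6, trials = 1, seed = 11)
  lay <- build_disc(disc_spec(5, 6, trials = 1, seed = 11))
  expect_identical(attr(lay, "ring_offset"), ref$beta)

  # with a real search, the symmetry/window pruning must not change the
  # selected offsets
  for (seed in 1:3) {
    ref <- build_disc_bruteforce(7, 7, trials = 25, seed = seed)
    lay <- build_disc(disc_spec(7, 7, trials = 25, seed = seed))
    expect_equal(attr(lay, "ring_offset"), ref$beta, tolerance = 1e-12)
  }
})

test_that("offsets are cumulative and confined to one arm sector", {
  lay <- build_disc(disc_spec(9, 6, trials = 40, seed = 2))
  beta <- attr(lay, "ring_offset")
  expect_true(all(beta >= 0 & beta < 2 * pi / 9))
  # arm 1's angle at ring n is the running sum of offsets
  for (ring in c(2L, 5L)) {
    ang <- atan2(lay$y, lay$x)[lay$n == ring & lay$phi == 1L]
    expect_equal((ang - sum(beta[seq_len(ring)])) %% (2 * pi), 0,
                 tolerance = 1e-9)
  }
})

test_that("nearest-neighbour profile matches the brute-force oracle", {
  lay <- build_disc(disc_spec(20, 12, trials = 20, seed = 3))
  expect_equal(ripplepond:::nn_dists(lay$x, lay$y),
               nn_bruteforce(lay$x, lay$y))

  prof <- nn_distance_profile(lay, 4)
  expect_true(all(prof$mean_nn > 0, na.rm = TRUE))
  expect_equal(sum(prof$n_neurons), nrow(lay))

  # single band, two-point disc: the only distance is origin-to-edge
  tiny <- build_disc(disc_spec(1, 2, trials = 1, seed = 1))
  expect_equal(nn_distance_profile(tiny, 1)$mean_nn, 1)
})

test_that("cell-binned nearest neighbours stay exact at realistic sizes", {
  lay <- build_disc(disc_spec(60, 60, trials = 5, seed = 8))
  idx <- c(1L, 57L, 600L, 1771L, nrow(lay))
  full <- ripplepond:::nn_dists(lay$x, lay$y)
  expect_equal(full[idx], nn_bruteforce(lay$x, lay$y)[idx])
})

test_that("empty bands are reported as missing, not as errors", {
  tiny <- build_disc(disc_spec(2, 3, trials = 5, seed = 4))
  prof <- nn_distance_profile(tiny, 10)
  expect_true(any(is.na(prof$mean_nn)))
  expect_equal(sum(prof$n_neurons), nrow(tiny))
})

test_that("disc layouts round-trip through CSV + JSON", {
  lay <- build_disc(disc_spec(10, 5, trials = 15, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_disc(lay, path)
  back <- read_disc(path)
  expect_equal(as.data.frame(back), as.data.frame(lay))
  expect_equal(attr(back, "ring_offset"), attr(lay, "ring_offset"))
  expect_equal(attr(back, "spec")$arms, 10L)
})
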