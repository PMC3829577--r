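lay84 <- build_disc(disc_spec(8, 4, trials = 20, seed = 1))

test_that("projection activates neurons by thresholded nearest-pixel samples", {
  expect_error(project_frame(matrix(0, 4, 6), lay84),
               class = "ripplepond_bad_image")

  fr0 <- project_frame(matrix(0, 64, 64), lay84, threshold = 0.5)
  expect_equal(fr0$m, 0L)

  fr1 <- project_frame(matrix(1, 64, 64), lay84, threshold = 0.5)
  expect_equal(fr1$m, 8L * 3L + 1L)
  expect_true(fr1$center_active)

  # a filled circle reaching exactly between rings 2 and 3 activates the
  # centre and rings 1..2 only: m = 2 * arms + 1
  r <- attr(lay84, "ring_radius")
  radius_px <- (r[3] + r[4]) / 2 * 32
  fr <- project_frame(circle_image(64, radius_px), lay84, threshold = 0.5)
  expect_equal(fr$m, 2L * 8L + 1L)
  expect_true(all(fr$ring_active[1:2, ]))
  expect_false(any(fr$ring_active[3, ]))
})

test_that("ripple emits each activation once, at its ring's exit step", {
  # lone activation at ring 3 exits at step 4
  act <- matrix(FALSE, 3, 8)
  act[3, 5] <- TRUE
  tp <- ripple(rpn_frame(act))
  expect_equal(tp$value, c(0L, 0L, 0L, 1L))

  # full disc: centre at step 1, then one full ring per step
  full <- ripple(rpn_frame(matrix(TRUE, 3, 8), center_active = TRUE))
  expect_equal(full$value, c(1L, 8L, 8L, 8L))
  expect_equal(sum(full$value), attr(full, "m"))

  empty <- ripple(rpn_frame(matrix(FALSE, 3, 8)))
  expect_equal(empty$value, rep(0L, 4))
  expect_equal(attr(empty, "m"), 0L)
})

test_that("optimized ripple matches the explicit shift-register simulation", {
  set.seed(10)
  for (i in 1:200) {
    fr <- random_frame(sample(1:12, 1), sample(2:12, 1), p = runif(1, 0.05, 0.9))
    expect_identical(ripple(fr)$value, ripple_reference(fr)$value)
  }
})

test_that("activation is conserved and the shutter trace drains to zero", {
  set.seed(11)
  for (i in 1:200) {
    fr <- random_frame(sample(1:10, 1), sample(2:10, 1), p = runif(1))
    tp <- ripple(fr)
    expect_identical(sum(tp$value), fr$m)
    inh <- inhibitory_trace(fr)
    expect_equal(inh$inh[1], fr$m)
    expect_true(all(diff(inh$inh) <= 0))
    expect_equal(inh$inh[fr$per_arm + 1L], 0L)
  }
})

test_that("the temporal pattern is invariant under arm rotation", {
  set.seed(12)
  for (i in 1:50) {
    fr <- random_frame(8, 6)
    j <- sample(0:7, 1)
    rotated <- rpn_frame(fr$ring_active[, c((j + 1):8, seq_len(j))[1:8], drop = FALSE],
                         center_active = fr$center_active)
    expect_identical(ripple(rotated)$value, ripple(fr)$value)
  }
})

test_that("halving a circle's radius roughly halves the pattern's duration", {
  lay <- build_disc(disc_spec(16, 16, trials = 20, seed = 2))
  full <- ripple(project_frame(circle_image(128, 63), lay, threshold = 0.5))
  half <- ripple(project_frame(circle_image(128, 31.5), lay, threshold = 0.5))
  last <- function(tp) max(which(tp$value > 0))
  # covered ring count scales with radius^2 under r_n ~ sqrt(n), so the
  # exit-time support shrinks to about a quarter of the steps
  expect_lt(last(half), last(full) / 2)
  expect_gt(attr(full, "m"), 3.5 * attr(half, "m"))
})

test_that("gated shuttering admits frames as soon as the disc clears", {
  lay <- build_disc(disc_spec(6, 8, trials = 10, seed = 3))
  r <- attr(lay, "ring_radius")
  small <- circle_image(64, (r[3] + r[4]) / 2 * 32)     # rings <= 2
  big <- circle_image(64, 33)                           # full disc

  # a single frame gives the same pattern in either mode
  g1 <- stream_run(list(big), lay, mode = "gated")
  p1 <- stream_run(list(big), lay, mode = "periodic")
  expect_identical(g1[[1]]$value, p1[[1]]$value)

  # second frame arrives at step 1 while the small first frame drains:
  # gated admits it at step 3 (= outermost active ring + 1), periodic at 8
  g2 <- stream_run(list(small, big), lay, arrivals = c(0L, 1L), mode = "gated")
  p2 <- stream_run(list(small, big), lay, arrivals = c(0L, 1L), mode = "periodic")
  expect_equal(attr(g2[[2]], "t0"), 3L)
  expect_equal(attr(p2[[2]], "t0"), 8L)

  # a steady stream of small frames: gated emits more patterns over the
  # same horizon because small frames clear early
  arrivals <- as.integer(seq(0, 40, by = 4))
  maps <- rep(list(small), length(arrivals))
  g <- stream_run(maps, lay, arrivals = arrivals, mode = "gated")
  p <- stream_run(maps, lay, arrivals = arrivals, mode = "periodic")
  expect_gt(length(g), length(p))

  expect_identical(stream_run(list(), lay), list())
  expect_error(stream_run(list(small, big), lay, arrivals = c(5L, 1L)),
               class = "ripplepond_bad_param")
})
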