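test_that("time-warp normalization resamples the support and divides by m", {
  # support already at target length with m = 1: values unchanged
  tp <- c(0, 1, 0, 0, 0)
  expect_equal(as.numeric(normalize_tp(tp, 1)), 1)

  # worked example: support [4, 4] of an m = 8 pattern resampled to 4 points
  expect_equal(as.numeric(normalize_tp(c(0, 0, 4, 4), 4)), rep(0.5, 4))

  # identity resample keeps a full-support pattern (m folded out)
  v <- c(2, 3, 1, 4)
  expect_equal(as.numeric(normalize_tp(v, 4)), v / 10)

  # idempotent on full-support normalized patterns
  once <- as.numeric(normalize_tp(v, 4))
  expect_equal(as.numeric(normalize_tp(once, 4)), once / sum(once),
               tolerance = 1e-9)

  expect_error(normalize_tp(c(0, 0, 0), 4), class = "ripplepond_empty_pattern")
})

test_that("similarity metrics match their definitions and reject degenerates", {
  u <- c(1, 2, 3, 5)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_error(cosine_similarity(u, rep(0, 4)),
               class = "ripplepond_undefined_similarity")
  expect_error(cosine_similarity(u, c(1, 2)), class = "ripplepond_bad_param")

  # monotone transforms preserve rank correlation
  expect_equal(spearman_rho(1:6, (1:6)^3), 1)
  expect_equal(spearman_rho(1:6, rev(1:6)), -1)
  # hand-enumerated mean ranks: u -> 1, 2.5, 2.5, 4; v -> 1, 2, 3.5, 3.5;
  # Pearson of those ranks is 5/6
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 3)), 5 / 6)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "ripplepond_undefined_similarity")

  # both metrics ignore positive rescaling
  v <- c(0.4, 0.1, 0.9, 0.2, 0.6)
  w <- c(0.3, 0.8, 0.2, 0.9, 0.1)
  expect_equal(cosine_similarity(3.7 * v, w), cosine_similarity(v, w))
  expect_equal(spearman_rho(v, 0.01 * w), spearman_rho(v, w))
})

lay16 <- build_disc(disc_spec(16, 16, trials = 20, seed = 5))

test_that("normalized patterns from nested circles are nearly collinear", {
  full <- ripple(project_frame(circle_image(128, 63), lay16, threshold = 0.5))
  half <- ripple(project_frame(circle_image(128, 31.5), lay16, threshold = 0.5))
  cs <- cosine_similarity(normalize_tp(full, 50), normalize_tp(half, 50))
  expect_gt(cs, 0.9)
})

test_that("invariance sweeps are exact at identity and deterministic", {
  ts <- make_test_set(4, size = 64, seed = 21)
  tab <- invariance_sweep(ts, lay16, "rotation", grid = c(0, pi / 7))
  expect_s3_class(tab, "similarity_table")
  expect_equal(tab$mean_cos[1], 1)
  expect_equal(tab$mean_rho[1], 1)
  expect_equal(tab$n_used[1], 4L)
  expect_true(all(tab$mean_cos >= -1 & tab$mean_cos <= 1))

  again <- invariance_sweep(ts, lay16, "rotation", grid = c(0, pi / 7))
  expect_identical(as.data.frame(tab), as.data.frame(again))

  expect_error(invariance_sweep(ts, lay16, "rotation", grid = numeric(0)),
               class = "ripplepond_bad_param")
})

test_that("rotating by one arm spacing returns near-identical similarity", {
  lay <- build_disc(disc_spec(32, 12, trials = 20, seed = 6))
  ts <- make_test_set(6, size = 96, seed = 22)
  tab <- invariance_sweep(ts, lay, "rotation", grid = c(0, 2 * pi / 32))
  expect_lt(abs(tab$mean_cos[2] - tab$mean_cos[1]), 0.02)
})

test_that("the period estimator recovers a known sinusoid and flags flat curves", {
  fake <- function(y, grid) {
    structure(tibble::tibble(magnitude = grid, mean_cos = y,
                             mean_rho = y, n_used = 1L),
              transform = "rotation", n_images = 1L, target_len = 10L,
              class = c("similarity_table", class(tibble::tibble())))
  }
  p <- 0.04
  grid <- seq(0, 3 * p, length.out = 61)
  tab <- fake(cos(2 * pi * grid / p), grid)
  expect_lt(abs(estimate_period(tab) - p), grid[2] - grid[1])

  # an added linear drift must not disturb the estimate
  tab_drift <- fake(cos(2 * pi * grid / p) - 3 * grid, grid)
  expect_lt(abs(estimate_period(tab_drift) - p), grid[2] - grid[1])

  expect_error(estimate_period(fake(rep(0.5, 61), grid)),
               class = "ripplepond_no_period")

  scale_tab <- fake(cos(grid), grid)
  attr(scale_tab, "transform") <- "scale"
  expect_error(estimate_period(scale_tab), class = "ripplepond_bad_param")
})

test_that("similarity tables round-trip and tidy/glance summarize them", {
  ts <- make_test_set(3, size = 64, seed = 23)
  tab <- invariance_sweep(ts, lay16, "translation", grid = c(0, 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_similarity(tab, path)
  back <- read_similarity(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_equal(attr(back, "transform"), "translation")

  long <- tidy(tab)
  expect_equal(nrow(long), 4L)
  expect_setequal(unique(long$metric), c("cosine", "spearman"))
  g <- glance(tab)
  expect_equal(g$transform, "translation")
  expect_equal(g$max_drop_cos, 1 - min(tab$mean_cos))
})
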