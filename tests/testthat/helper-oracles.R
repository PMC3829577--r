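# Independent reference implementations used as oracles. These are written
# naively (brute force, explicit loops) and must stay independent of the
# package's optimized code paths.

# Brute-force placement search: scores every candidate offset by the minimum
# distance over ALL candidate-ring neurons x ALL already-placed neurons.
build_disc_bruteforce <- function(arms, per_arm, trials, seed) {
  r_raw <- sqrt(seq_len(per_arm - 1L))
  sector <- 2 * pi / arms
  arm_base <- sector * (seq_len(arms) - 1L)
  set.seed(seed)
  beta <- numeric(per_arm - 1L)
  cum <- 0
  placed <- matrix(c(0, 0), ncol = 2)          # start with the centre
  for (n in seq_len(per_arm - 1L)) {
    delta <- stats::runif(trials, 0, sector)
    score <- numeric(trials)
    for (j in seq_len(trials)) {
      ang <- arm_base + cum + delta[j]
      cand <- cbind(r_raw[n] * cos(ang), r_raw[n] * sin(ang))
      dmin <- Inf
      for (a in seq_len(nrow(cand))) {
        d <- sqrt((placed[, 1] - cand[a, 1])^2 + (placed[, 2] - cand[a, 2])^2)
        dmin <- min(dmin, min(d))
      }
      # scores that tie in exact arithmetic (all of ring 1, symmetric pairs)
      # must not be separated by evaluation-order rounding noise
      score[j] <- signif(dmin, 12)
    }
    best <- which.max(score)
    beta[n] <- delta[best]
    cum <- cum + beta[n]
    ang <- arm_base + cum
    placed <- rbind(placed, cbind(r_raw[n] * cos(ang), r_raw[n] * sin(ang)))
  }
  list(beta = beta, positions = placed / r_raw[per_arm - 1L])
}

# All-pairs nearest-neighbour distances.
nn_bruteforce <- function(x, y) {
  vapply(seq_along(x), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    min(d[-i])
  }, numeric(1))
}

# Direct 2D convolution with an explicit DoG kernel, reflective padding.
dog_bruteforce <- function(img, sc, ss) {
  half <- max(ceiling(3 * sc), ceiling(3 * ss))
  # each Gaussian is truncated at 3 sigma of its own scale, then embedded in
  # the common support
  gk <- function(s) {
    h <- max(1L, ceiling(3 * s))
    k <- exp(-(-h:h)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- numeric(2L * half + 1L)
    out[half + 1L + (-h:h)] <- k
    out
  }
  kern <- outer(gk(sc), gk(sc)) - outer(gk(ss), gk(ss))
  n <- nrow(img)
  reflect <- function(i) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
  }
  out <- matrix(0, n, ncol(img))
  for (r in seq_len(n)) for (cc in seq_len(ncol(img))) {
    acc <- 0
    for (dr in -half:half) for (dc in -half:half) {
      acc <- acc + kern[dr + half + 1L, dc + half + 1L] *
        img[reflect(r + dr), reflect(cc + dc)]
    }
    out[r, cc] <- acc
  }
  out
}

# Exact lossless counter-clockwise 90-degree rotation of a square matrix.
rot90_ccw <- function(m) {
  n <- nrow(m)
  o <- matrix(0, n, n)
  for (r in seq_len(n)) o[, r] <- m[r, n:1]
  o
}

random_frame <- function(arms, per_arm, p = 0.3) {
  rpn_frame(matrix(stats::runif((per_arm - 1L) * arms) < p, per_arm - 1L, arms),
            center_active = stats::runif(1) < p)
}

# filled circle raster (binary), radius in pixels about the image centre
circle_image <- function(size, radius) {
  cx <- (size + 1) / 2
  xs <- matrix(rep(seq_len(size) - cx, each = size), size, size)
  ys <- matrix(rep(cx - seq_len(size), times = size), size, size)
  (xs^2 + ys^2 <= radius^2) * 1
}
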