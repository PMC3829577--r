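#' Specify a spiral RPN disc
#'
#' A ripple pond network (RPN) disc consists of `arms` spiral arms of
#' unit-delay relay neurons with `per_arm` neurons along each arm; the
#' innermost neuron (ring index `n = 0`) is a single neuron shared by all
#' arms, so a disc holds `arms * (per_arm - 1) + 1` neurons in total.
#' Ring `n` sits at radius `sqrt(n)` (normalized so the outermost ring is at
#' radius 1), which keeps the areal density of neurons approximately uniform
#' across the disc — the property that makes temporal patterns from rescaled
#' images time-warped copies of each other rather than different patterns.
#'
#' @param arms Number of spiral arms (Phi), a positive integer.
#' @param per_arm Neurons per arm (N) counting the shared central neuron;
#'   at least 2.
#' @param trials Number of random candidate angular offsets evaluated per
#'   ring during the placement search.
#' @param seed Integer seed driving the placement search RNG.
#'
#' @return A `disc_spec` list with elements `arms`, `per_arm`, `trials`,
#'   `seed`.
#' @seealso [build_disc()]
#' @export
#' @examples
#' disc_spec(arms = 8, per_arm = 4)
disc_spec <- function(arms, per_arm, trials = 1000L, seed = 1L) {
  arms <- as.integer(arms)
  per_arm <- as.integer(per_arm)
  trials <- as.integer(trials)
  seed <- as.integer(seed)
  if (is.na(arms) || arms < 1L) {
    rlang::abort("`arms` must be a positive integer.", class = "ripplepond_bad_spec")
  }
  if (is.na(per_arm) || per_arm < 2L) {
    rlang::abort("`per_arm` must be an integer >= 2.", class = "ripplepond_bad_spec")
  }
  if (is.na(trials) || trials < 1L) {
    rlang::abort("`trials` must be a positive integer.", class = "ripplepond_bad_spec")
  }
  structure(
    list(arms = arms, per_arm = per_arm, trials = trials, seed = seed),
    class = "disc_spec"
  )
}

#' @export
print.disc_spec <- function(x, ...) {
  cat(sprintf(
    "<disc_spec> Phi = %d arms, N = %d neurons/arm (%d neurons), %d trials/ring, seed %d\n",
    x$arms, x$per_arm, x$arms * (x$per_arm - 1L) + 1L, x$trials, x$seed
  ))
  invisible(x)
}

#' Build a spiral RPN disc layout
#'
#' Places neurons on the unit disc with a randomized max-min-distance search.
#' Ring `n` (radius proportional to `sqrt(n)`) is rotated relative to ring
#' `n - 1` by an offset `beta_n`: for each ring, `trials` candidate offsets
#' are drawn uniformly from `[0, 2*pi/arms)` (larger offsets are redundant by
#' arm symmetry), each candidate is scored by the minimum Euclidean distance
#' from the candidate ring to every already-placed neuron, and the candidate
#' with the largest minimum distance wins (ties broken in favour of the first
#' candidate drawn). The offsets are cumulative, so the arms spiral.
#'
#' Because the candidate ring and the already-placed set are both exactly
#' `arms`-fold rotationally symmetric, the minimum pairwise distance is
#' attained at any single candidate arm, and rings radially farther away than
#' an upper bound on the achievable score can never attain it; the search
#' exploits both facts but is exactly equivalent to the brute-force all-pairs
#' scoring (same RNG stream, same selected offsets).
#'
#' @param spec A [disc_spec()].
#' @return A tibble of class `disc_layout` with one row per neuron and
#'   columns `n` (ring index, 0-based), `phi` (arm index, 1-based; 0 for the
#'   shared central neuron), `x`, `y` (unit-disc Cartesian coordinates).
#'   Attributes: `spec`, `ring_radius` (length `per_arm`), `ring_offset`
#'   (the `beta_n`, length `per_arm - 1`).
#' @export
#' @examples
#' layout <- build_disc(disc_spec(arms = 8, per_arm = 4, trials = 50, seed = 7))
#' nrow(layout)  # 8 * 3 + 1 = 25 neurons
build_disc <- function(spec) {
  stopifnot(inherits(spec, "disc_spec"))
  arms <- spec$arms
  nper <- spec$per_arm
  r_raw <- sqrt(seq_len(nper - 1L))     # unnormalized ring radii, rings 1..N-1
  sector <- 2 * pi / arms
  arm_base <- sector * (seq_len(arms) - 1L)

  beta <- numeric(nper - 1L)
  cum <- 0
  # placed points per ring (angles of arm 1; other arms are rotations)
  ring_angle <- numeric(nper - 1L)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  for (n in seq_len(nper - 1L)) {
    delta <- stats::runif(spec$trials, 0, sector)
    if (n == 1L) {
      # only the central neuron is placed; every candidate scores sqrt(1)
      best <- 1L
    } else {
      rn <- r_raw[n]
      # upper bound on the achievable max-min score: distance to the nearest
      # neuron of ring n-1 is at most the chord subtended by half an arm sector
      rp <- r_raw[n - 1L]
      ub <- sqrt(rn^2 + rp^2 - 2 * rn * rp * cos(pi / arms))
      keep <- which(r_raw[seq_len(n - 1L)] >= rn - ub)
      # nearby placed points, all arms
      ang <- outer(ring_angle[keep], arm_base, `+`)
      px <- as.vector(r_raw[keep] * cos(ang))
      py <- as.vector(r_raw[keep] * sin(ang))
      cand_ang <- cum + delta
      cx <- rn * cos(cand_ang)
      cy <- rn * sin(cand_ang)
      d2 <- outer(cx, px, `-`)^2 + outer(cy, py, `-`)^2
      score <- sqrt(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))])
      if (rn - ub <= 0) score <- pmin(score, rn)  # central neuron in range
      best <- which.max(score)
    }
    beta[n] <- delta[best]
    cum <- cum + beta[n]
    ring_angle[n] <- cum
  }

  r_norm <- r_raw / r_raw[nper - 1L]
  n_idx <- rep(seq_len(nper - 1L), each = arms)
  phi_idx <- rep(seq_len(arms), times = nper - 1L)
  ang <- ring_angle[n_idx] + arm_base[phi_idx]
  out <- tibble::tibble(
    n = c(0L, n_idx),
    phi = c(0L, phi_idx),
    x = c(0, r_norm[n_idx] * cos(ang)),
    y = c(0, r_norm[n_idx] * sin(ang))
  )
  new_disc_layout(out, spec, ring_radius = c(0, r_norm), ring_offset = beta)
}

new_disc_layout <- function(df, spec, ring_radius, ring_offset) {
  structure(
    df,
    spec = spec,
    ring_radius = ring_radius,
    ring_offset = ring_offset,
    class = c("disc_layout", class(tibble::tibble()))
  )
}

#' @export
print.disc_layout <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "<disc_layout> Phi = %d arms, N = %d neurons/arm, %d neurons\n",
    spec$arms, spec$per_arm, nrow(x)
  ))
  NextMethod()
}

disc_arms <- function(layout) attr(layout, "spec")$arms
disc_per_arm <- function(layout) attr(layout, "spec")$per_arm

#' Nearest-neighbour distances for a point set
#'
#' Spatial cell binning keeps the cost near-linear in the number of points,
#' which matters for full-size discs (~40k neurons); results are exact.
#'
#' @param x,y Coordinates.
#' @return Numeric vector of each point's distance to its nearest other point.
#' @keywords internal
#' @noRd
nn_dists <- function(x, y) {
  p <- length(x)
  if (p < 2L) rlang::abort("need at least two points")
  if (p <= 2000L) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    return(unname(apply(d, 1L, min)))
  }
  # cell size ~ 3x mean spacing on a unit disc
  h <- 3 * sqrt(pi / p)
  cx <- floor((x - min(x)) / h)
  cy <- floor((y - min(y)) / h)
  ncx <- max(cx) + 1L
  key <- cx + cy * ncx
  ord <- order(key)
  res <- rep(Inf, p)
  cells <- split(ord, key[ord])
  cell_of <- as.character(key)
  for (ck in names(cells)) {
    idx <- cells[[ck]]
    k <- as.integer(ck)
    kx <- k %% ncx
    ky <- k %/% ncx
    neigh <- integer(0)
    for (dxc in -1:1) for (dyc in -1:1) {
      nk <- as.character(kx + dxc + (ky + dyc) * ncx)
      if ((kx + dxc) >= 0 && (kx + dxc) < ncx && !is.null(cells[[nk]])) {
        neigh <- c(neigh, cells[[nk]])
      }
    }
    d2 <- outer(x[idx], x[neigh], `-`)^2 + outer(y[idx], y[neigh], `-`)^2
    d2[cbind(seq_along(idx), match(idx, neigh))] <- Inf
    res[idx] <- sqrt(apply(d2, 1L, min))
  }
  # a point whose true nearest neighbour lies outside the 3x3 neighbourhood
  # would report > h; fall back to brute force for those (rare to none)
  sus <- which(res > h)
  for (i in sus) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    res[i] <- sqrt(min(d2))
  }
  res
}

#' Radial profile of nearest-neighbour distances
#'
#' Validates the approximate uniformity of the spiral placement: on a uniform
#' disc the mean nearest-neighbour distance is roughly constant with radius,
#' whereas a log-polar placement would show a strong radial trend.
#'
#' @param layout A [build_disc()] layout.
#' @param n_bands Number of radial bands partitioning (0, 1].
#' @param partition `"area"` (default) for equal-area bands — the natural
#'   partition when validating areal density — or `"width"` for equal
#'   radial width. Note that the innermost region is crowded by
#'   construction: every ring carries all `arms` neurons, so within-ring
#'   spacing shrinks toward the center even though per-area counts stay
#'   uniform.
#' @return A tibble with columns `band_mid` (band mid-radius), `mean_nn`
#'   (mean nearest-neighbour distance of neurons in the band; `NA` for an
#'   empty band) and `n_neurons`.
#' @export
nn_distance_profile <- function(layout, n_bands = 5L,
                                partition = c("area", "width")) {
  stopifnot(inherits(layout, "disc_layout"), n_bands >= 1L)
  partition <- match.arg(partition)
  r <- sqrt(layout$x^2 + layout$y^2)
  nn <- nn_dists(layout$x, layout$y)
  edges <- seq(0, 1, length.out = n_bands + 1L)
  if (partition == "area") edges <- sqrt(edges)
  band <- pmin(pmax(findInterval(r, edges, left.open = TRUE), 1L), n_bands)
  band[r == 0] <- 1L
  tibble::tibble(
    band_mid = (edges[-1] + edges[-(n_bands + 1L)]) / 2,
    mean_nn = vapply(seq_len(n_bands), function(b) {
      v <- nn[band == b]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1)),
    n_neurons = vapply(seq_len(n_bands), function(b) sum(band == b), integer(1))
  )
}

#' Neuron counts in equal-area annuli
#'
#' @param layout A [build_disc()] layout.
#' @param n_annuli Number of equal-area annuli covering the unit disc.
#' @return A tibble with columns `annulus`, `r_inner`, `r_outer`, `count`.
#' @export
annulus_counts <- function(layout, n_annuli = 5L) {
  stopifnot(inherits(layout, "disc_layout"), n_annuli >= 1L)
  r <- sqrt(layout$x^2 + layout$y^2)
  r_edge <- sqrt(seq(0, 1, length.out = n_annuli + 1L))
  idx <- pmin(pmax(findInterval(r, r_edge, left.open = TRUE), 1L), n_annuli)
  idx[r == 0] <- 1L
  tibble::tibble(
    annulus = seq_len(n_annuli),
    r_inner = r_edge[-(n_annuli + 1L)],
    r_outer = r_edge[-1],
    count = vapply(seq_len(n_annuli), function(b) sum(idx == b), integer(1))
  )
}

#' Write / read a disc layout
#'
#' The layout is stored as a plain CSV (`n, phi, x, y`) plus a JSON sidecar
#' (`<path>.json`) holding the spec and the per-ring offsets so the layout
#' round-trips losslessly.
#'
#' @param layout A `disc_layout`.
#' @param path CSV path.
#' @return `write_disc()` returns `path` invisibly; `read_disc()` returns the
#'   reconstructed `disc_layout`.
#' @export
write_disc <- function(layout, path) {
  stopifnot(inherits(layout, "disc_layout"))
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE)
  spec <- attr(layout, "spec")
  jsonlite::write_json(
    list(
      arms = spec$arms, per_arm = spec$per_arm, trials = spec$trials,
      seed = spec$seed,
      ring_radius = attr(layout, "ring_radius"),
      ring_offset = attr(layout, "ring_offset")
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_disc
#' @export
read_disc <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- disc_spec(meta$arms, meta$per_arm, meta$trials, meta$seed)
  new_disc_layout(
    tibble::tibble(n = as.integer(df$n), phi = as.integer(df$phi),
                   x = df$x, y = df$y),
    spec, ring_radius = meta$ring_radius, ring_offset = meta$ring_offset
  )
}
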