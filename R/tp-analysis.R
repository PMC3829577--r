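#' Time-warp normalize a temporal pattern
#'
#' A rescaled image produces a temporal pattern that is a time- and
#' magnitude-scaled copy of the original's. The downstream memory is
#' time-warp invariant; this operation emulates that by resampling the
#' pattern's support (first through last nonzero step) linearly onto a
#' fixed length and dividing the values by the frame magnitude `m` — the
#' normalization cue the inhibitory neuron delivers before the pattern
#' itself arrives.
#'
#' @param tp An `rpn_tp` from [ripple()], or a plain numeric vector of
#'   per-step counts (in which case `m` defaults to its sum).
#' @param target_len Output length (default 200).
#' @return A numeric vector of length `target_len` with attribute `m`.
#' @export
#' @examples
#' fr <- rpn_frame(matrix(TRUE, 3, 8), center_active = TRUE)
#' normalize_tp(ripple(fr), target_len = 8)
normalize_tp <- function(tp, target_len = 200L) {
  if (inherits(tp, "rpn_tp")) {
    values <- tp$value
    m <- attr(tp, "m")
  } else {
    values <- as.numeric(tp)
    m <- sum(values)
  }
  stopifnot(target_len >= 1L)
  nz <- which(values != 0)
  if (length(nz) == 0L) {
    rlang::abort("cannot normalize an all-zero temporal pattern.",
                 class = "ripplepond_empty_pattern")
  }
  support <- values[min(nz):max(nz)] / m
  if (length(support) == 1L) {
    out <- rep(support, target_len)
  } else {
    out <- stats::approx(seq_along(support), support, n = target_len)$y
  }
  attr(out, "m") <- m
  out
}

#' Cosine similarity of two equal-length vectors
#'
#' @param u,v Numeric vectors of equal length; neither all-zero.
#' @return `sum(u * v) / (norm(u) * norm(v))`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    rlang::abort("`u` and `v` must have equal length.",
                 class = "ripplepond_bad_param")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    rlang::abort("cosine similarity undefined for a zero vector.",
                 class = "ripplepond_undefined_similarity")
  }
  sum(u * v) / (nu * nv)
}

#' Spearman rank correlation of two equal-length vectors
#'
#' Pearson correlation of average-ranked values (ties get mean ranks),
#' computed via [stats::cor()].
#'
#' @param u,v Numeric vectors of equal length >= 2, neither constant.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L) {
    rlang::abort("`u` and `v` must have equal length >= 2.",
                 class = "ripplepond_bad_param")
  }
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    rlang::abort("Spearman rho undefined for a constant sequence.",
                 class = "ripplepond_undefined_similarity")
  }
  stats::cor(u, v, method = "spearman")
}

# image -> normalized TP through the standard single-disc pipeline;
# pix_idx/ring_of are the cached projection tables from disc_sampler().
# warp = TRUE resamples the nonzero support (time-warp alignment, needed to
# compare patterns across scales); warp = FALSE resamples the whole time
# axis, preserving where on the disc the activation sat.
image_to_ntp <- function(img, sampler, threshold, target_len,
                         sigma_center = 1, sigma_surround = 2, warp = TRUE) {
  fm <- abs(dog_highpass(img, sigma_center, sigma_surround))
  vals <- fm[sampler$pix_idx]
  active <- vals > threshold
  m <- sum(active)
  if (m == 0L) return(NULL)
  tp <- c(as.integer(active[1L]),
          tabulate(sampler$ring_of[active & sampler$ring_of > 0L],
                   nbins = sampler$per_arm - 1L))
  if (!warp) {
    tp <- tp / m
    if (length(tp) == target_len) return(tp)
    return(stats::approx(seq_along(tp), tp, n = target_len)$y)
  }
  nz <- which(tp != 0)
  support <- tp[min(nz):max(nz)] / m
  if (length(support) == 1L) rep(support, target_len)
  else stats::approx(seq_along(support), support, n = target_len)$y
}

# cache nearest-pixel projection of a layout onto a side x side raster
disc_sampler <- function(layout, side) {
  cx <- (side + 1) / 2
  rad <- side / 2
  ci <- pmin(pmax(round(cx + layout$x * rad), 1), side)
  ri <- pmin(pmax(round(cx - layout$y * rad), 1), side)
  list(
    pix_idx = (ci - 1L) * side + ri,     # column-major linear index
    ring_of = layout$n,
    per_arm = disc_per_arm(layout)
  )
}

#' Sweep similarity of temporal patterns across an image transform
#'
#' For each image and each transform magnitude: transform the raster
#' ([transform_image()]), difference-of-Gaussians filter both versions,
#' project them onto the disc, ripple, normalize both patterns, and record
#' cosine similarity and Spearman rho between them. The table holds
#' per-magnitude means across images; images whose transformed pattern is
#' empty at a magnitude are excluded from that magnitude's mean (`n_used`
#' reports the count retained).
#'
#' Normalization policy: patterns are always magnitude-normalized by `m`
#' and brought to `target_len` points, but the *time-warp* (support)
#' alignment that stretches the nonzero span onto the full axis is only
#' meaningful when the transform changes object size. Under `time_warp =
#' "auto"` (default) scale sweeps compare support-aligned patterns —
#' without the warp, a rescaled object would trivially dissimilar — while
#' rotation and translation sweeps compare the patterns on their native
#' time axis, where the warp would mask genuine radial redistribution of
#' activation.
#'
#' @param images List of square numeric matrices (or a [make_test_set()]
#'   tibble, whose `image` column is used).
#' @param layout A [build_disc()] layout.
#' @param transform `"rotation"` (radians), `"scale"` (factor) or
#'   `"translation"` (pixels along +x).
#' @param grid Transform magnitudes.
#' @param target_len Normalized pattern length.
#' @param threshold Activation threshold on the rectified feature map.
#' @param sigma_center,sigma_surround DoG sigmas in pixels.
#' @param method Raster resampling method for the transform.
#' @param time_warp `"auto"` (support-align only for scale sweeps),
#'   `"always"`, or `"never"`.
#' @return A `similarity_table` tibble with columns `magnitude`,
#'   `mean_cos`, `mean_rho`, `n_used`; attributes `transform`, `n_images`,
#'   `target_len`.
#' @export
invariance_sweep <- function(images, layout,
                             transform = c("rotation", "scale", "translation"),
                             grid, target_len = 200L, threshold = 1e-6,
                             sigma_center = 1, sigma_surround = 2,
                             method = "nearest",
                             time_warp = c("auto", "always", "never")) {
  transform <- match.arg(transform)
  time_warp <- match.arg(time_warp)
  warp <- switch(time_warp, auto = transform == "scale",
                 always = TRUE, never = FALSE)
  if (is.data.frame(images)) images <- images$image
  if (length(grid) == 0L) {
    rlang::abort("`grid` must be non-empty.", class = "ripplepond_bad_param")
  }
  stopifnot(inherits(layout, "disc_layout"))
  side <- nrow(images[[1L]])
  sampler <- disc_sampler(layout, side)

  base <- lapply(images, image_to_ntp, sampler = sampler,
                 threshold = threshold, target_len = target_len,
                 sigma_center = sigma_center, sigma_surround = sigma_surround,
                 warp = warp)

  res <- purrr::map(grid, function(g) {
    cs <- rep(NA_real_, length(images))
    rs <- rep(NA_real_, length(images))
    for (i in seq_along(images)) {
      if (is.null(base[[i]])) next
      timg <- switch(transform,
        rotation = transform_image(images[[i]], rotation = g, method = method),
        scale = transform_image(images[[i]], scale = g, method = method),
        translation = transform_image(images[[i]], shift = c(g, 0),
                                      method = method)
      )
      ntp <- image_to_ntp(timg, sampler, threshold, target_len,
                          sigma_center, sigma_surround, warp = warp)
      if (is.null(ntp)) next
      cs[i] <- cosine_similarity(base[[i]], ntp)
      rs[i] <- suppressWarnings(stats::cor(base[[i]], ntp, method = "spearman"))
    }
    ok <- !is.na(cs)
    tibble::tibble(
      magnitude = g,
      mean_cos = mean(cs[ok]),
      mean_rho = mean(rs[ok], na.rm = TRUE),
      n_used = sum(ok)
    )
  })
  out <- dplyr::bind_rows(res)
  structure(
    out,
    transform = transform, n_images = length(images), target_len = target_len,
    class = c("similarity_table", class(tibble::tibble()))
  )
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> transform = %s, %d images\n",
              attr(x, "transform"), attr(x, "n_images")))
  NextMethod()
}

#' Dominant period of a rotation-similarity curve
#'
#' Estimates the repeat interval of `mean_cos` versus rotation angle: the
#' curve is linearly detrended (pixel resampling adds a slow drift on top
#' of the arm-spacing periodicity) and the dominant frequency is read off
#' the periodogram; the period is the grid span divided by that cycle
#' count. On a disc with `arms` spiral arms the expected period is
#' `2 * pi / arms`.
#'
#' @param table A `similarity_table` from a rotation sweep with a uniform
#'   grid covering at least two periods.
#' @return The period, in the grid's units (radians).
#' @export
estimate_period <- function(table) {
  stopifnot(inherits(table, "similarity_table"))
  if (!identical(attr(table, "transform"), "rotation")) {
    rlang::abort("`estimate_period()` needs a rotation sweep.",
                 class = "ripplepond_bad_param")
  }
  g <- table$magnitude
  step <- diff(g)
  if (length(step) < 3L || max(abs(step - step[1])) > 1e-9 * max(abs(step))) {
    rlang::abort("rotation grid must be uniform.", class = "ripplepond_bad_param")
  }
  y <- table$mean_cos
  n <- length(y)
  yd <- stats::residuals(stats::lm(y ~ seq_len(n)))
  # drop the closing endpoint: a grid from 0 over k full periods duplicates
  # phase 0, and an integer-cycle window avoids spectral leakage
  yd <- yd[-n]
  if (stats::sd(yd) < 1e-12 * (1 + stats::sd(y))) {
    rlang::abort("no periodicity detected (flat similarity curve).",
                 class = "ripplepond_no_period")
  }
  sp <- Mod(stats::fft(yd))^2
  ks <- seq_len(floor((n - 1L) / 2L))
  k <- ks[which.max(sp[ks + 1L])]
  (n - 1L) * step[1] / k
}

#' Write / read a similarity table
#'
#' CSV columns `magnitude, mean_cos, mean_rho, n_used` plus a JSON sidecar
#' with the transform label and sweep metadata.
#'
#' @param table A `similarity_table`.
#' @param path CSV path.
#' @export
write_similarity <- function(table, path) {
  stopifnot(inherits(table, "similarity_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  jsonlite::write_json(
    list(transform = attr(table, "transform"),
         n_images = attr(table, "n_images"),
         target_len = attr(table, "target_len")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    tibble::as_tibble(df),
    transform = meta$transform, n_images = meta$n_images,
    target_len = meta$target_len,
    class = c("similarity_table", class(tibble::tibble()))
  )
}
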