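#' Build a bank of feature-by-density channels
#'
#' Each channel pairs a rectified radial Gabor orientation with a disc
#' density: the density scales the per-arm neuron count, so lower-density
#' discs emit shorter, earlier, low-resolution versions of the full
#' temporal pattern — usable downstream for normalization or early
#' categorization. Each density disc is built by re-running the placement
#' search at the reduced per-arm count (not by subsampling the full disc),
#' which preserves the uniform-density guarantee at every density.
#'
#' @param full_spec A [disc_spec()] for the full-density disc.
#' @param alphas Radial Gabor orientation offsets in radians.
#' @param densities Fractions of the full per-arm count, in `(0, 1]`;
#'   `round(density * (per_arm))` must be at least 2 (round-half-up).
#' @param gabor Base [gabor_params()] shared by all channels.
#' @return A tibble of class `channel_bank` with columns `feature`
#'   (channel label), `alpha`, `density`, `per_arm`, and a list-column
#'   `disc` of built layouts.
#' @export
#' @examples
#' ch <- build_channels(disc_spec(16, 8, trials = 20, seed = 1),
#'                      alphas = c(0, pi / 4, pi / 2),
#'                      densities = c(1, 0.5))
#' nrow(ch)  # 3 orientations x 2 densities = 6 channels
build_channels <- function(full_spec, alphas, densities = 1,
                           gabor = gabor_params()) {
  stopifnot(inherits(full_spec, "disc_spec"))
  if (length(alphas) == 0L || length(densities) == 0L) {
    rlang::abort("`alphas` and `densities` must be non-empty.",
                 class = "ripplepond_bad_param")
  }
  if (any(densities <= 0 | densities > 1)) {
    rlang::abort("`densities` must lie in (0, 1].", class = "ripplepond_bad_param")
  }
  per_arm <- as.integer(floor(densities * full_spec$per_arm + 0.5))  # round half up
  if (any(per_arm < 2L)) {
    rlang::abort("a density yields fewer than 2 neurons per arm.",
                 class = "ripplepond_bad_param")
  }
  discs <- lapply(per_arm, function(np) {
    build_disc(disc_spec(full_spec$arms, np, full_spec$trials, full_spec$seed))
  })
  grid <- tidyr::expand_grid(
    alpha = alphas,
    di = seq_along(densities)
  )
  structure(
    tibble::tibble(
      feature = sprintf("radial_gabor_%g", round(grid$alpha * 180 / pi, 3)),
      alpha = grid$alpha,
      density = densities[grid$di],
      per_arm = per_arm[grid$di],
      disc = discs[grid$di]
    ),
    gabor = gabor,
    class = c("channel_bank", class(tibble::tibble()))
  )
}

#' @export
`[.channel_bank` <- function(x, ...) {
  out <- NextMethod()
  attr(out, "gabor") <- attr(x, "gabor")
  class(out) <- class(x)
  out
}

#' Run an image through a multi-channel disc bank
#'
#' Per channel: radial Gabor feature map (rectified) -> disc projection ->
#' ripple. The result is a multi-channel spatio-temporal pattern; each
#' channel's temporal pattern obeys its own disc's conservation law
#' (`sum(TP) = m`), and lower-density channels finish earlier.
#'
#' @param img Square numeric matrix.
#' @param channels A [build_channels()] bank.
#' @param threshold Activation threshold on the rectified feature maps.
#' @return A tibble of class `rpn_stp`: the bank's columns plus list-column
#'   `tp` (each an `rpn_tp`) and `m`, `last_step` summaries.
#' @export
run_multidisc <- function(img, channels, threshold = 1e-6) {
  check_image(img)
  stopifnot(inherits(channels, "channel_bank"))
  if (nrow(channels) == 0L) {
    rlang::abort("`channels` must be non-empty.", class = "ripplepond_bad_param")
  }
  gabor <- attr(channels, "gabor")
  # one feature map per distinct orientation, shared across densities
  fmaps <- lapply(unique(channels$alpha), function(a) {
    p <- gabor
    p$alpha <- a
    abs(radial_gabor(img, p))
  })
  names(fmaps) <- as.character(unique(channels$alpha))
  tps <- purrr::map2(channels$alpha, channels$disc, function(a, disc) {
    ripple(project_frame(fmaps[[as.character(a)]], disc, threshold))
  })
  out <- dplyr::mutate(
    tibble::as_tibble(channels[, c("feature", "alpha", "density", "per_arm")]),
    tp = tps,
    m = vapply(tps, attr, integer(1), "m"),
    last_step = vapply(tps, function(tp) {
      nz <- which(tp$value != 0)
      if (length(nz) == 0L) 0L else as.integer(max(nz))
    }, integer(1))
  )
  structure(out, class = c("rpn_stp", class(tibble::tibble())))
}

#' @export
print.rpn_stp <- function(x, ...) {
  cat(sprintf("<rpn_stp> %d channels\n", nrow(x)))
  NextMethod()
}
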