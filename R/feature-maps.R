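#' @keywords internal
#' @noRd
check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    rlang::abort(sprintf("`%s` must be a numeric matrix.", arg),
                 class = "ripplepond_bad_image")
  }
  if (anyNA(img) || any(!is.finite(img))) {
    rlang::abort(sprintf("`%s` contains non-finite values.", arg),
                 class = "ripplepond_bad_image")
  }
  invisible(img)
}

gaussian_kernel_1d <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# reflective (mirror) padding along rows
reflect_pad_rows <- function(img, h) {
  nr <- nrow(img)
  idx <- c(rev(seq_len(h) + 1L), seq_len(nr), nr - seq_len(h))
  img[idx, , drop = FALSE]
}

# separable convolution with a symmetric 1D kernel, reflective boundaries
conv_sep <- function(img, k) {
  h <- (length(k) - 1L) %/% 2L
  one_pass <- function(m) {
    p <- reflect_pad_rows(m, h)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[seq_len(nrow(m)) + (j - 1L), , drop = FALSE]
    }
    out
  }
  t(one_pass(t(one_pass(img))))
}

#' Gaussian blur with reflective boundaries
#'
#' @param img Numeric matrix.
#' @param sigma Standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img)
  if (!is.numeric(sigma) || sigma <= 0) {
    rlang::abort("`sigma` must be positive.", class = "ripplepond_bad_param")
  }
  conv_sep(img, gaussian_kernel_1d(sigma))
}

#' Difference-of-Gaussians high-pass filter
#'
#' Subtracts a wide (surround) Gaussian blur from a narrow (center) one,
#' removing the DC component and low spatial frequencies: constant regions
#' map to (numerically) zero and edges to signed bands. This is the
#' pre-processing applied to every raster before projection onto a disc.
#'
#' @param img Numeric matrix with intensities in `[0, 1]`.
#' @param sigma_center Center Gaussian sigma in pixels (default 1).
#' @param sigma_surround Surround Gaussian sigma in pixels (default 2);
#'   must exceed `sigma_center`.
#' @return A numeric matrix of signed responses, same shape as `img`, with
#'   attribute `channel = "dog"`.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[12:20, 12:20] <- 1
#' fm <- dog_highpass(img)
#' range(fm)
dog_highpass <- function(img, sigma_center = 1, sigma_surround = 2) {
  check_image(img)
  if (!is.numeric(sigma_center) || !is.numeric(sigma_surround) ||
      sigma_center <= 0 || sigma_surround <= sigma_center) {
    rlang::abort("need `sigma_surround` > `sigma_center` > 0.",
                 class = "ripplepond_bad_param")
  }
  out <- gaussian_blur(img, sigma_center) - gaussian_blur(img, sigma_surround)
  attr(out, "channel") <- "dog"
  out
}

#' Gabor filter parameters
#'
#' @param alpha Radial orientation offset in radians: the kernel at a pixel
#'   whose position angle about the center is `beta` is oriented at
#'   `theta = alpha + beta`. `alpha = 0` selects features tangent to radii
#'   ("spoke-aligned"), `alpha = pi/2` features orthogonal to them.
#' @param wavelength Carrier wavelength in pixels.
#' @param envelope_sigma Gaussian envelope sigma in pixels.
#' @param aspect Envelope aspect ratio (gamma); 1 is isotropic.
#' @param phase Carrier phase in radians (0 = even/cosine kernel).
#' @return A `gabor_params` list.
#' @export
gabor_params <- function(alpha = 0, wavelength = 8, envelope_sigma = 3,
                         aspect = 0.8, phase = 0) {
  if (wavelength <= 0 || envelope_sigma <= 0 || aspect <= 0) {
    rlang::abort("`wavelength`, `envelope_sigma` and `aspect` must be positive.",
                 class = "ripplepond_bad_param")
  }
  structure(
    list(alpha = alpha, wavelength = wavelength,
         envelope_sigma = envelope_sigma, aspect = aspect, phase = phase),
    class = "gabor_params"
  )
}

# center-relative pixel coordinates, +y up (mathematical convention)
pixel_coords <- function(nr, nc) {
  cx <- (nc + 1) / 2
  cy <- (nr + 1) / 2
  list(
    x = matrix(rep(seq_len(nc) - cx, each = nr), nr, nc),
    y = matrix(rep(cy - seq_len(nr), times = nc), nr, nc)
  )
}

#' Radial Gabor filtering
#'
#' Computes, at every pixel, the inner product of the local neighbourhood
#' with a Gabor kernel whose orientation is `alpha + beta`, where `beta` is
#' the angle of the pixel's position about the image center. Because the
#' orientation co-rotates with position angle, the response map is
#' rotation-equivariant about the center: rotating the input rotates the
#' response map. A Cartesian (fixed-orientation) Gabor map, by contrast, is
#' not — see [cartesian_gabor()] for the negative control.
#'
#' The per-pixel orientation cosine/sine are taken directly as `x/r`, `y/r`
#' so equivariance under exact 90-degree grid rotations holds to machine
#' precision.
#'
#' @param img Numeric matrix (square for disc work, any shape accepted).
#' @param params A [gabor_params()].
#' @param center Optional `c(x, y)` center in pixel units (column, row from
#'   bottom); defaults to the image center.
#' @return Numeric matrix of signed responses, same shape as `img`.
#' @export
radial_gabor <- function(img, params = gabor_params(), center = NULL) {
  check_image(img)
  stopifnot(inherits(params, "gabor_params"))
  nr <- nrow(img)
  nc <- ncol(img)
  half <- max(1L, ceiling(3 * params$envelope_sigma))
  if (2L * half + 1L > min(nr, nc)) {
    rlang::abort("Gabor kernel larger than the image.",
                 class = "ripplepond_bad_param")
  }
  co <- pixel_coords(nr, nc)
  if (!is.null(center)) {
    cx0 <- (nc + 1) / 2
    cy0 <- (nr + 1) / 2
    if (center[1] < 1 || center[1] > nc || center[2] < 1 || center[2] > nr) {
      rlang::abort("`center` lies outside the image.", class = "ripplepond_bad_param")
    }
    co$x <- co$x - (center[1] - cx0)
    co$y <- co$y - (center[2] - cy0)
  }
  r <- sqrt(co$x^2 + co$y^2)
  # position angle beta: cos = x/r, sin = y/r; the kernel orientation is
  # theta = alpha + beta, composed via angle-sum identities
  inv <- ifelse(r == 0, 0, 1 / r)
  cb <- ifelse(r == 0, 1, co$x * inv)
  sb <- co$y * inv
  ca <- cos(params$alpha)
  sa <- sin(params$alpha)
  ct <- ca * cb - sa * sb
  st <- sa * cb + ca * sb

  pad <- function(m, h) {
    nr0 <- nrow(m); nc0 <- ncol(m)
    out <- matrix(0, nr0 + 2L * h, nc0 + 2L * h)
    out[h + seq_len(nr0), h + seq_len(nc0)] <- m
    out
  }
  pimg <- pad(img, half)
  offs <- seq(-half, half)
  resp <- matrix(0, nr, nc)
  sig2 <- 2 * params$envelope_sigma^2
  g2 <- params$aspect^2
  w0 <- 2 * pi / params$wavelength
  rows <- half + seq_len(nr)
  cols <- half + seq_len(nc)
  for (dy in offs) for (dx in offs) {
    # kernel sample at offset (dx, dy) in +y-up coordinates, rotated into
    # the local frame: u along the carrier, v along the envelope minor axis
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    w <- exp(-(u^2 + g2 * v^2) / sig2) * cos(w0 * u + params$phase)
    # +y up means image row decreases as dy increases
    resp <- resp + w * pimg[rows - dy, cols + dx]
  }
  attr(resp, "channel") <- sprintf("radial_gabor_%g", round(params$alpha * 180 / pi, 3))
  resp
}

#' Cartesian Gabor filtering (fixed orientation)
#'
#' Standard Gabor convolution with a single, position-independent
#' orientation `theta = alpha`. Provided as the negative control for
#' rotation equivariance: its response map rotates its *content* but not its
#' orientation structure, so it fails the equivariance property that
#' [radial_gabor()] satisfies.
#'
#' @inheritParams radial_gabor
#' @return Numeric matrix of signed responses.
#' @export
cartesian_gabor <- function(img, params = gabor_params()) {
  check_image(img)
  stopifnot(inherits(params, "gabor_params"))
  nr <- nrow(img); nc <- ncol(img)
  half <- max(1L, ceiling(3 * params$envelope_sigma))
  if (2L * half + 1L > min(nr, nc)) {
    rlang::abort("Gabor kernel larger than the image.",
                 class = "ripplepond_bad_param")
  }
  offs <- seq(-half, half)
  ct <- cos(params$alpha); st <- sin(params$alpha)
  sig2 <- 2 * params$envelope_sigma^2
  g2 <- params$aspect^2
  w0 <- 2 * pi / params$wavelength
  pimg <- matrix(0, nr + 2L * half, nc + 2L * half)
  pimg[half + seq_len(nr), half + seq_len(nc)] <- img
  rows <- half + seq_len(nr); cols <- half + seq_len(nc)
  resp <- matrix(0, nr, nc)
  for (dy in offs) for (dx in offs) {
    u <- dx * ct + dy * st
    v <- -dx * st + dy * ct
    w <- exp(-(u^2 + g2 * v^2) / sig2) * cos(w0 * u + params$phase)
    resp <- resp + w * pimg[rows - dy, cols + dx]
  }
  attr(resp, "channel") <- sprintf("cartesian_gabor_%g", round(params$alpha * 180 / pi, 3))
  resp
}

#' Bank of rectified radial Gabor channels
#'
#' One rectified (absolute-value) radial Gabor feature map per orientation
#' offset. Rectification precedes disc projection because disc neurons are
#' binary-activated by any sufficiently strong response of either sign.
#'
#' @param img Numeric matrix.
#' @param alphas Radial orientation offsets in radians.
#' @param params Base [gabor_params()]; its `alpha` is overridden per channel.
#' @return Named list of rectified feature-map matrices
#'   (`radial_gabor_<deg>` for each alpha).
#' @export
#' @examples
#' img <- matrix(runif(64^2), 64, 64)
#' maps <- gabor_bank(img, alphas = c(0, pi / 4, pi / 2))
#' names(maps)
gabor_bank <- function(img, alphas, params = gabor_params()) {
  if (length(alphas) == 0L) {
    rlang::abort("`alphas` must be non-empty.", class = "ripplepond_bad_param")
  }
  maps <- lapply(alphas, function(a) {
    p <- params
    p$alpha <- a
    m <- abs(radial_gabor(img, p))
    attr(m, "channel") <- sprintf("radial_gabor_%g", round(a * 180 / pi, 3))
    m
  })
  names(maps) <- vapply(maps, attr, character(1), "channel")
  maps
}
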