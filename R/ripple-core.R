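#' Project a feature map onto a disc
#'
#' The unit disc is inscribed in the (square) map: disc radius equals half
#' the image side and the disc center sits at the image center. Each neuron
#' samples the pixel nearest its Cartesian position (+y up) and is active
#' iff the sampled value exceeds `threshold`. The total active count `m` is
#' the frame's magnitude — the quantity the inhibitory neuron reports at
#' projection time and the normalization cue attached to the temporal
#' pattern downstream.
#'
#' @param map Square numeric matrix (a feature map or raw image).
#' @param layout A [build_disc()] layout.
#' @param threshold Activation threshold; a neuron fires iff its sampled
#'   value is strictly greater. The default `1e-6` realizes "any positive
#'   response activates" on rectified feature maps while ignoring
#'   floating-point residue in flat regions.
#' @param sampling `"nearest"` (default) or `"bilinear"`.
#' @return An `rpn_frame`: list with `ring_active` (logical
#'   `(per_arm - 1) x arms` matrix), `center_active`, `m`, `t0` (admission
#'   step, 0 until set by [stream_run()]) and the disc dimensions.
#' @export
project_frame <- function(map, layout, threshold = 1e-6,
                          sampling = c("nearest", "bilinear")) {
  check_image(map, "map")
  stopifnot(inherits(layout, "disc_layout"))
  sampling <- match.arg(sampling)
  if (nrow(map) != ncol(map)) {
    rlang::abort("`map` must be square for disc projection.",
                 class = "ripplepond_bad_image")
  }
  if (!is.finite(threshold)) {
    rlang::abort("`threshold` must be finite.", class = "ripplepond_bad_param")
  }
  vals <- sample_disc(map, layout, sampling)
  new_frame(vals > threshold, layout)
}

# sample the map at every neuron position; returns values ordered as layout rows
sample_disc <- function(map, layout, sampling = "nearest") {
  s <- nrow(map)
  cx <- (s + 1) / 2
  rad <- s / 2
  px <- cx + layout$x * rad        # column
  py <- cx - layout$y * rad        # row (+y up)
  if (sampling == "nearest") {
    ci <- pmin(pmax(round(px), 1), s)
    ri <- pmin(pmax(round(py), 1), s)
    map[cbind(ri, ci)]
  } else {
    x0 <- pmin(pmax(floor(px), 1), s - 1L)
    y0 <- pmin(pmax(floor(py), 1), s - 1L)
    fx <- pmin(pmax(px - x0, 0), 1)
    fy <- pmin(pmax(py - y0, 0), 1)
    (1 - fx) * (1 - fy) * map[cbind(y0, x0)] +
      fx * (1 - fy) * map[cbind(y0, x0 + 1L)] +
      (1 - fx) * fy * map[cbind(y0 + 1L, x0)] +
      fx * fy * map[cbind(y0 + 1L, x0 + 1L)]
  }
}

# build an rpn_frame from a logical activation vector in layout row order
new_frame <- function(active, layout, t0 = 0L) {
  arms <- disc_arms(layout)
  nper <- disc_per_arm(layout)
  ring <- matrix(FALSE, nper - 1L, arms)
  ring[cbind(layout$n[-1L], layout$phi[-1L])] <- active[-1L]
  structure(
    list(
      ring_active = ring,
      center_active = isTRUE(active[1L]),
      m = sum(ring) + as.integer(active[1L]),
      t0 = as.integer(t0),
      arms = arms, per_arm = nper
    ),
    class = "rpn_frame"
  )
}

#' Construct a disc frame from explicit activations
#'
#' Mainly useful for tests and synthetic experiments that bypass image
#' projection.
#'
#' @param ring_active Logical `(per_arm - 1) x arms` matrix: row `n` holds
#'   ring `n`, column `phi` arm `phi`.
#' @param center_active Logical, activation of the shared central neuron.
#' @param t0 Admission step.
#' @return An `rpn_frame`.
#' @export
rpn_frame <- function(ring_active, center_active = FALSE, t0 = 0L) {
  stopifnot(is.matrix(ring_active), is.logical(ring_active))
  structure(
    list(
      ring_active = ring_active,
      center_active = isTRUE(center_active),
      m = sum(ring_active) + as.integer(isTRUE(center_active)),
      t0 = as.integer(t0),
      arms = ncol(ring_active), per_arm = nrow(ring_active) + 1L
    ),
    class = "rpn_frame"
  )
}

#' @export
print.rpn_frame <- function(x, ...) {
  cat(sprintf("<rpn_frame> Phi = %d, N = %d, m = %d, t0 = %d\n",
              x$arms, x$per_arm, x$m, x$t0))
  invisible(x)
}

new_tp <- function(values, m, arms, per_arm, dt = 1, t0 = 0L, mode = "single") {
  structure(
    tibble::tibble(step = seq_along(values), value = as.integer(values)),
    m = as.integer(m), dt = dt, arms = arms, per_arm = per_arm,
    t0 = as.integer(t0), mode = mode,
    class = c("rpn_tp", class(tibble::tibble()))
  )
}

#' @export
print.rpn_tp <- function(x, ...) {
  cat(sprintf("<rpn_tp> m = %d, dt = %g, %d steps (Phi = %d, N = %d)\n",
              attr(x, "m"), attr(x, "dt"), nrow(x), attr(x, "arms"),
              attr(x, "per_arm")))
  NextMethod()
}

#' Ripple a frame inward and emit its temporal pattern
#'
#' Activation shifts one ring inward per unit step: a neuron active on ring
#' `n` at admission exits through the summing neuron at step `n + 1`, the
#' central neuron's activation at step 1. The temporal pattern TP(t) counts
#' the activations exiting at each step `t = 1..per_arm`; every initial
#' activation exits exactly once, so `sum(TP) = m`. The pattern is invariant
#' under any rotation of the arm indices — the disc-level statement of the
#' network's rotational invariance.
#'
#' This closed form is what the inward unit-delay shift register computes;
#' [ripple_reference()] runs the explicit state-array simulation and is used
#' as the independent oracle in the test-suite.
#'
#' @param frame An `rpn_frame`.
#' @return An `rpn_tp` tibble (`step`, `value`) of length `per_arm`, with
#'   attributes `m`, `dt`, `arms`, `per_arm`, `t0`.
#' @export
#' @examples
#' fr <- rpn_frame(matrix(TRUE, 3, 8), center_active = TRUE)
#' ripple(fr)$value  # 1, 8, 8, 8 — center first, then rings 1..3
ripple <- function(frame) {
  stopifnot(inherits(frame, "rpn_frame"))
  # ring n exits at step n + 1, the central neuron at step 1
  tp <- c(as.integer(frame$center_active), rowSums(frame$ring_active))
  new_tp(tp, frame$m, frame$arms, frame$per_arm, t0 = frame$t0)
}

#' Explicit shift-register simulation of the ripple
#'
#' Updates the full `(per_arm - 1) x arms` state array one unit delay at a
#' time: ring `n - 1` at step `t` copies ring `n` at step `t - 1`; ring 1 and
#' the central neuron feed the summing neuron. Slower than [ripple()] but
#' follows the network dynamics literally; kept as the reference
#' implementation.
#'
#' @param frame An `rpn_frame`.
#' @return An `rpn_tp`, identical to `ripple(frame)`.
#' @export
ripple_reference <- function(frame) {
  stopifnot(inherits(frame, "rpn_frame"))
  state <- frame$ring_active           # rows are rings 1..N-1
  nper <- frame$per_arm
  tp <- integer(nper)
  tp[1L] <- as.integer(frame$center_active)   # the centre exits at step 1
  for (t in seq_len(nper)[-1L]) {
    tp[t] <- sum(state[1L, ])                 # ring 1 feeds the summing neuron
    state <- rbind(state[-1L, , drop = FALSE],
                   matrix(FALSE, 1L, frame$arms))   # inward unit-delay shift
  }
  new_tp(tp, frame$m, frame$arms, frame$per_arm, t0 = frame$t0)
}

#' Inhibitory (shutter) neuron trace
#'
#' The inhibitory neuron carries the net activity of all neurons on the
#' disc: `Inh(t) = m - sum(TP(1..t))`, the number of activations still
#' travelling inward after step `t`. It starts at `m` when the frame is
#' admitted, never increases, and reaches 0 by step `per_arm`, at which
#' point the visual pathway is unblocked and the next frame may be admitted.
#'
#' @param frame An `rpn_frame`.
#' @return A tibble (`step` = 0..per_arm, `inh`).
#' @export
inhibitory_trace <- function(frame) {
  tp <- ripple(frame)
  tibble::tibble(
    step = 0:frame$per_arm,
    inh = as.integer(frame$m - c(0L, cumsum(tp$value)))
  )
}

#' Run a stream of frames through the disc with a shutter
#'
#' Models a continuously refreshing sensor feeding the disc. In `periodic`
#' mode a new frame is admitted every `per_arm` steps regardless of disc
#' content. In `gated` mode the inhibitory neuron acts as an asynchronous
#' shutter: the next frame is admitted at the first step at which the disc
#' has fully cleared (`Inh = 0`), so small objects — which clear early — are
#' followed sooner and the effective frame rate adapts to image size.
#' Frames arriving while the disc is busy wait; when an admission slot
#' opens, the most recently arrived pending frame wins and earlier unserved
#' frames are dropped (the sensor has refreshed past them).
#'
#' @param maps List of square feature-map matrices.
#' @param layout A [build_disc()] layout.
#' @param arrivals Integer vector of arrival steps, non-decreasing, same
#'   length as `maps`.
#' @param threshold Activation threshold, as in [project_frame()].
#' @param mode `"gated"` or `"periodic"`.
#' @return List of `rpn_tp` objects, one per admitted frame, each tagged
#'   with its admission step in attribute `t0`.
#' @export
stream_run <- function(maps, layout, arrivals = rep(0L, length(maps)),
                       threshold = 1e-6, mode = c("gated", "periodic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "disc_layout"))
  if (length(maps) == 0L) return(list())
  arrivals <- as.integer(arrivals)
  if (length(arrivals) != length(maps) || is.unsorted(arrivals)) {
    rlang::abort("`arrivals` must be non-decreasing, one per map.",
                 class = "ripplepond_bad_param")
  }
  nper <- disc_per_arm(layout)
  frames <- lapply(maps, project_frame, layout = layout, threshold = threshold)
  out <- list()
  i <- 1L                      # next frame not yet considered
  n_f <- length(frames)
  free_at <- arrivals[1L]      # first step at which the disc can admit
  if (mode == "periodic") free_at <- 0L
  while (i <= n_f) {
    if (mode == "periodic") {
      # admission slots at multiples of per_arm
      slot <- free_at
      pending <- which(arrivals <= slot)
      pending <- pending[pending >= i]
      if (length(pending) == 0L) {
        # skip empty slots until the next arrival
        k <- ceiling((arrivals[i] - slot) / nper)
        slot <- slot + k * nper
        pending <- which(arrivals <= slot)
        pending <- pending[pending >= i]
      }
      pick <- max(pending)
      admit <- slot
      free_at <- slot + nper
    } else {
      admit <- max(free_at, arrivals[i])
      pending <- which(arrivals <= admit)
      pending <- pending[pending >= i]
      pick <- max(pending)
      fr <- frames[[pick]]
      # disc clears when the outermost active ring has exited
      occ <- which(rowSums(fr$ring_active) > 0L)
      busy <- if (length(occ) > 0L) max(occ) + 1L else as.integer(fr$center_active)
      free_at <- admit + busy
    }
    fr <- frames[[pick]]
    fr$t0 <- as.integer(admit)
    tp <- ripple(fr)
    attr(tp, "mode") <- mode
    out[[length(out) + 1L]] <- tp
    i <- pick + 1L
  }
  out
}
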