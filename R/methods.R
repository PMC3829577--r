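#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a disc layout
#'
#' @param x A `disc_layout`.
#' @param ... Unused.
#' @return A tibble (`n`, `phi`, `x`, `y`, `radius`, `angle`).
#' @method tidy disc_layout
#' @export
tidy.disc_layout <- function(x, ...) {
  dplyr::mutate(
    tibble::as_tibble(x),
    radius = sqrt(.data$x^2 + .data$y^2),
    angle = atan2(.data$y, .data$x)
  )
}

#' @rdname tidy.disc_layout
#' @method glance disc_layout
#' @export
glance.disc_layout <- function(x, ...) {
  spec <- attr(x, "spec")
  nn <- nn_distance_profile(x, n_bands = 5L)
  tibble::tibble(
    arms = spec$arms, per_arm = spec$per_arm, n_neurons = nrow(x),
    trials = spec$trials, seed = spec$seed,
    nn_band_ratio = max(nn$mean_nn, na.rm = TRUE) /
      min(nn$mean_nn, na.rm = TRUE)
  )
}

#' Tidy a temporal pattern
#'
#' @param x An `rpn_tp`.
#' @param ... Unused.
#' @return A tibble (`step`, `value`, `m`).
#' @method tidy rpn_tp
#' @export
tidy.rpn_tp <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), m = attr(x, "m"))
}

#' @rdname tidy.rpn_tp
#' @method glance rpn_tp
#' @export
glance.rpn_tp <- function(x, ...) {
  nz <- which(x$value != 0)
  tibble::tibble(
    m = attr(x, "m"), dt = attr(x, "dt"),
    arms = attr(x, "arms"), per_arm = attr(x, "per_arm"),
    t0 = attr(x, "t0"),
    first_step = if (length(nz)) min(nz) else NA_integer_,
    last_step = if (length(nz)) max(nz) else NA_integer_
  )
}

#' @rdname tidy.similarity_table
#' @method glance similarity_table
#' @export
glance.similarity_table <- function(x, ...) {
  tibble::tibble(
    transform = attr(x, "transform"),
    n_images = attr(x, "n_images"),
    target_len = attr(x, "target_len"),
    min_cos = min(x$mean_cos), min_rho = min(x$mean_rho),
    max_drop_cos = 1 - min(x$mean_cos), max_drop_rho = 1 - min(x$mean_rho)
  )
}

#' Tidy a similarity table
#'
#' @param x A `similarity_table`.
#' @param ... Unused.
#' @return A long tibble (`magnitude`, `metric`, `similarity`, `n_used`).
#' @method tidy similarity_table
#' @export
tidy.similarity_table <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::rename(tibble::as_tibble(x), cosine = "mean_cos",
                  spearman = "mean_rho"),
    cols = c("cosine", "spearman"),
    names_to = "metric", values_to = "similarity"
  )
}

#' Plot a disc layout
#'
#' @param object A `disc_layout`.
#' @param ... Unused.
#' @return A ggplot: neuron positions coloured by arm, showing the spiral
#'   structure of the placement.
#' @method autoplot disc_layout
#' @export
autoplot.disc_layout <- function(object, ...) {
  df <- tibble::as_tibble(object)
  spec <- attr(object, "spec")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = factor(.data$phi))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Spiral disc, %d arms x %d neurons/arm",
                      spec$arms, spec$per_arm),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a temporal pattern
#'
#' @param object An `rpn_tp`.
#' @param ... Unused.
#' @return A ggplot step chart of TP(t) with `m` in the subtitle.
#' @method autoplot rpn_tp
#' @export
autoplot.rpn_tp <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(
      title = "Temporal pattern",
      subtitle = sprintf("m = %d activations", attr(object, "m")),
      x = "time step", y = "exits per step"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an invariance sweep
#'
#' @param object A `similarity_table`.
#' @param ... Unused.
#' @return A ggplot of mean cosine and Spearman similarity against the
#'   transform magnitude.
#' @method autoplot similarity_table
#' @export
autoplot.similarity_table <- function(object, ...) {
  unit <- switch(attr(object, "transform"),
                 rotation = "rotation (rad)",
                 scale = "scale factor",
                 translation = "shift (px)")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$magnitude, .data$similarity,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      title = sprintf("Temporal-pattern similarity under %s",
                      attr(object, "transform")),
      x = unit, y = "mean similarity", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a multi-channel spatio-temporal pattern
#'
#' @param object An `rpn_stp` from [run_multidisc()].
#' @param ... Unused.
#' @return A ggplot faceting each channel's temporal pattern; lower-density
#'   channels visibly finish earlier.
#' @method autoplot rpn_stp
#' @export
autoplot.rpn_stp <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::mutate(
      tibble::as_tibble(object)[, c("feature", "density", "tp")],
      tp = lapply(.data$tp, tibble::as_tibble)
    ),
    "tp"
  )
  df$channel <- sprintf("%s @ %.2g", df$feature, df$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = "time step", y = "exits per step") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
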