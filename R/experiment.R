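#' Configuration for the full invariance experiment
#'
#' Collects every tunable of the single-disc pipeline in one serializable
#' object so an experiment can be reproduced from its config alone.
#'
#' @param arms,per_arm,trials Disc dimensions and placement-search effort.
#' @param n_images Number of synthetic test images.
#' @param size Image side in pixels.
#' @param threshold Activation threshold on rectified feature maps.
#' @param sigma_center,sigma_surround DoG sigmas in pixels.
#' @param target_len Normalized temporal-pattern length.
#' @param rotation_grid,scale_grid,translation_grid Sweep grids (radians,
#'   scale factors, pixels).
#' @param seed Master seed (disc search and image set).
#' @return A `run_config` list.
#' @export
run_config <- function(arms = 200L, per_arm = 200L, trials = 1000L,
                       n_images = 30L, size = 200L, threshold = 1e-6,
                       sigma_center = 1, sigma_surround = 2,
                       target_len = 200L,
                       rotation_grid = seq(0, 4 * pi / 200, length.out = 33L),
                       scale_grid = seq(0.4, 1, by = 0.1),
                       translation_grid = seq(0, 40, by = 5),
                       seed = 42L) {
  structure(
    list(arms = as.integer(arms), per_arm = as.integer(per_arm),
         trials = as.integer(trials), n_images = as.integer(n_images),
         size = as.integer(size), threshold = threshold,
         sigma_center = sigma_center, sigma_surround = sigma_surround,
         target_len = as.integer(target_len),
         rotation_grid = rotation_grid, scale_grid = scale_grid,
         translation_grid = translation_grid, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the three-transform invariance experiment
#'
#' Generates (or reuses) the synthetic image set, builds the disc, and runs
#' rotation, scale and translation sweeps through the standard pipeline
#' (DoG filter, disc projection, ripple, time-warp normalization, cosine
#' and Spearman similarity). With `out_dir` set, writes the three tables as
#' CSV+JSON, a config snapshot, and a log recording the disc dimensions,
#' seed, thresholds and package version beside them.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param images Optional pre-built image list or [make_test_set()] tibble;
#'   generated from the config seed when `NULL`.
#' @param layout Optional pre-built [build_disc()] layout matching the
#'   config.
#' @return A named list of three `similarity_table`s
#'   (`rotation`, `scale`, `translation`).
#' @export
run_figure_experiment <- function(config = run_config(), out_dir = NULL,
                                  images = NULL, layout = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(images)) {
    images <- make_test_set(config$n_images, size = config$size,
                            seed = config$seed)
  }
  if (is.data.frame(images)) images <- images$image
  if (is.null(layout)) {
    layout <- build_disc(disc_spec(config$arms, config$per_arm,
                                   config$trials, config$seed))
  }
  sweeps <- list(rotation = config$rotation_grid,
                 scale = config$scale_grid,
                 translation = config$translation_grid)
  out <- purrr::imap(sweeps, function(grid, tr) {
    invariance_sweep(images, layout, transform = tr, grid = grid,
                     target_len = config$target_len,
                     threshold = config$threshold,
                     sigma_center = config$sigma_center,
                     sigma_surround = config$sigma_surround)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in names(out)) {
      write_similarity(out[[tr]], file.path(out_dir, paste0(tr, ".csv")))
    }
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(
      c(sprintf("ripplepond %s", as.character(utils::packageVersion("ripplepond"))),
        sprintf("disc: Phi=%d N=%d trials=%d seed=%d", config$arms,
                config$per_arm, config$trials, config$seed),
        sprintf("images: n=%d size=%d", config$n_images, config$size),
        sprintf("pipeline: dog(%g,%g) threshold=%g target_len=%d",
                config$sigma_center, config$sigma_surround, config$threshold,
                config$target_len),
        sprintf("R %s", as.character(getRversion()))),
      file.path(out_dir, "run.log")
    )
  }
  out
}
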