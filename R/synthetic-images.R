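# Embedded stroke-vector font (no system-font dependency): each glyph is a
# set of polylines on a 2 x 4 design box, y up. Deliberately angular; the
# experiments only need distinct, centered, binary-ish glyph silhouettes.
stroke_font <- local({
  g <- list(
    "A" = list(c(0,0, 1,4, 2,0), c(0.5,1.5, 1.5,1.5)),
    "B" = list(c(0,0, 0,4, 1.5,4, 2,3.2, 1.5,2, 0,2), c(1.5,2, 2,1, 1.5,0, 0,0)),
    "C" = list(c(2,3.5, 1.2,4, 0.5,3.5, 0,2.5, 0,1.5, 0.5,0.5, 1.2,0, 2,0.5)),
    "D" = list(c(0,0, 0,4, 1.2,4, 2,3, 2,1, 1.2,0, 0,0)),
    "E" = list(c(2,0, 0,0, 0,4, 2,4), c(0,2, 1.5,2)),
    "F" = list(c(0,0, 0,4, 2,4), c(0,2, 1.4,2)),
    "G" = list(c(2,3.5, 1.2,4, 0.4,3.4, 0,2, 0.4,0.6, 1.2,0, 2,0.4, 2,1.8, 1.1,1.8)),
    "H" = list(c(0,0, 0,4), c(2,0, 2,4), c(0,2, 2,2)),
    "I" = list(c(1,0, 1,4), c(0.4,4, 1.6,4), c(0.4,0, 1.6,0)),
    "J" = list(c(2,4, 2,1, 1.4,0, 0.6,0, 0,1)),
    "K" = list(c(0,0, 0,4), c(2,4, 0,1.8), c(0.7,2.6, 2,0)),
    "L" = list(c(0,4, 0,0, 2,0)),
    "M" = list(c(0,0, 0,4, 1,2, 2,4, 2,0)),
    "N" = list(c(0,0, 0,4, 2,0, 2,4)),
    "O" = list(c(0.6,0, 1.4,0, 2,0.8, 2,3.2, 1.4,4, 0.6,4, 0,3.2, 0,0.8, 0.6,0)),
    "P" = list(c(0,0, 0,4, 1.5,4, 2,3.2, 1.5,2.2, 0,2.2)),
    "Q" = list(c(0.6,0, 1.4,0, 2,0.8, 2,3.2, 1.4,4, 0.6,4, 0,3.2, 0,0.8, 0.6,0),
               c(1.2,0.9, 2,0)),
    "R" = list(c(0,0, 0,4, 1.5,4, 2,3.2, 1.5,2.2, 0,2.2), c(0.8,2.2, 2,0)),
    "S" = list(c(2,3.5, 1.3,4, 0.5,4, 0,3.3, 0.5,2.4, 1.5,1.8, 2,1, 1.5,0, 0.6,0, 0,0.5)),
    "T" = list(c(1,0, 1,4), c(0,4, 2,4)),
    "U" = list(c(0,4, 0,1, 0.6,0, 1.4,0, 2,1, 2,4)),
    "V" = list(c(0,4, 1,0, 2,4)),
    "W" = list(c(0,4, 0.5,0, 1,3, 1.5,0, 2,4)),
    "X" = list(c(0,0, 2,4), c(0,4, 2,0)),
    "Y" = list(c(0,4, 1,2, 2,4), c(1,2, 1,0)),
    "Z" = list(c(0,4, 2,4, 0,0, 2,0)),
    "0" = list(c(0.6,0, 1.4,0, 2,0.8, 2,3.2, 1.4,4, 0.6,4, 0,3.2, 0,0.8, 0.6,0),
               c(0.4,0.8, 1.6,3.2)),
    "1" = list(c(0.5,3.2, 1.2,4, 1.2,0), c(0.5,0, 1.8,0)),
    "2" = list(c(0,3.3, 0.6,4, 1.5,4, 2,3.3, 1.8,2.4, 0,0, 2,0)),
    "3" = list(c(0,4, 2,4, 1,2.4, 1.8,1.8, 2,1, 1.4,0, 0.4,0, 0,0.6)),
    "4" = list(c(1.5,0, 1.5,4, 0,1.3, 2,1.3)),
    "5" = list(c(2,4, 0,4, 0,2.3, 1.3,2.4, 2,1.6, 2,0.8, 1.3,0, 0.4,0, 0,0.5)),
    "6" = list(c(1.8,4, 0.8,3.2, 0.2,2, 0,1, 0.6,0, 1.5,0, 2,0.9, 1.5,1.8, 0.4,1.8, 0,1)),
    "7" = list(c(0,4, 2,4, 0.8,0)),
    "8" = list(c(1,2.1, 0.4,2.5, 0.3,3.4, 1,4, 1.7,3.4, 1.6,2.5, 1,2.1,
                 0.3,1.6, 0.2,0.6, 1,0, 1.8,0.6, 1.7,1.6, 1,2.1)),
    "9" = list(c(0.2,0, 1.2,0.8, 1.8,2, 2,3, 1.4,4, 0.5,4, 0,3.1, 0.5,2.2, 1.6,2.2, 2,3))
  )
  lapply(g, function(strokes) {
    lapply(strokes, function(s) matrix(s, ncol = 2, byrow = TRUE))
  })
})

# distance from pixels (px, py) to segment (x1,y1)-(x2,y2), vectorized
seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# rasterize polylines (in pixel coordinates, y up) with soft 1 px edges
draw_strokes <- function(size, strokes, width) {
  co <- pixel_coords(size, size)
  px <- co$x + (size + 1) / 2
  py <- co$y + (size + 1) / 2
  img <- matrix(0, size, size)
  for (s in strokes) {
    for (i in seq_len(nrow(s) - 1L)) {
      d <- seg_dist(px, py, s[i, 1], s[i, 2], s[i + 1, 1], s[i + 1, 2])
      img <- pmax(img, pmin(pmax(width / 2 + 0.5 - d, 0), 1))
    }
  }
  img
}

# even-odd point-in-polygon, vectorized over pixels
in_polygon <- function(px, py, vx, vy) {
  k <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- k
  for (i in seq_len(k)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# 2x supersampled fill of an inside() predicate over center-relative coords
fill_aa <- function(size, inside_fn) {
  s2 <- 2L * size
  cx <- (s2 + 1) / 2
  px <- matrix(rep(seq_len(s2) - cx, each = s2), s2, s2) / 2
  py <- matrix(rep(cx - seq_len(s2), times = s2), s2, s2) / 2
  m <- matrix(as.numeric(inside_fn(px, py)), s2, s2)
  (m[seq(1, s2, 2), seq(1, s2, 2)] + m[seq(2, s2, 2), seq(1, s2, 2)] +
     m[seq(1, s2, 2), seq(2, s2, 2)] + m[seq(2, s2, 2), seq(2, s2, 2)]) / 4
}

scale_strokes <- function(strokes, height, cx, cy, aspect = 1) {
  # design box is 2 x 4, y up; scale to `height`, center at (cx, cy)
  sc <- height / 4
  lapply(strokes, function(s) {
    cbind(cx + (s[, 1] - 1) * sc * aspect, cy + (s[, 2] - 2) * sc)
  })
}

#' Recipe for a synthetic centered test image
#'
#' The generator emulates a mixed test corpus of centered 200 x 200
#' grayscale rasters: letters, digits, short words, geometric shapes, and —
#' standing in for photographic faces and fish, which are not
#' redistributable — parametric radial-harmonic blobs with interior
#' features and fish-like silhouettes (ellipse body, triangle tail, eye).
#' All images are binary-ish with softly anti-aliased edges, deterministic
#' given the seed, and re-centered so the foreground centroid lies within
#' 2 px of the image center.
#'
#' @param kind One of `"letter"`, `"digit"`, `"word"`, `"shape"`, `"blob"`,
#'   `"silhouette"`.
#' @param size Image side in pixels.
#' @param seed Integer seed selecting the kind-specific parameters.
#' @return An `image_recipe` list.
#' @export
image_recipe <- function(kind = c("letter", "digit", "word", "shape", "blob",
                                  "silhouette"),
                         size = 200L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, size = as.integer(size), seed = as.integer(seed)),
            class = "image_recipe")
}

render_kind <- function(kind, size, seed) {
  set.seed(seed)
  c0 <- (size + 1) / 2
  switch(
    kind,
    letter = {
      ch <- sample(LETTERS, 1L)
      draw_strokes(size, scale_strokes(stroke_font[[ch]], 0.65 * size, c0, c0),
                   width = 0.085 * size)
    },
    digit = {
      ch <- sample(as.character(0:9), 1L)
      draw_strokes(size, scale_strokes(stroke_font[[ch]], 0.65 * size, c0, c0),
                   width = 0.085 * size)
    },
    word = {
      k <- sample(3:4, 1L)
      chs <- sample(LETTERS, k, replace = TRUE)
      h <- 0.34 * size
      pitch <- 0.62 * h
      xs <- c0 + (seq_len(k) - (k + 1) / 2) * pitch
      img <- matrix(0, size, size)
      for (i in seq_len(k)) {
        img <- pmax(img, draw_strokes(
          size, scale_strokes(stroke_font[[chs[i]]], h, xs[i], c0), 0.05 * size))
      }
      img
    },
    shape = {
      which_shape <- sample(c("circle", "polygon", "star", "rect", "ring"), 1L)
      r <- size * stats::runif(1, 0.2, 0.3)
      switch(
        which_shape,
        circle = fill_aa(size, function(px, py) px^2 + py^2 < r^2),
        ring = {
          r <- size * stats::runif(1, 0.24, 0.3)
          r2 <- r * stats::runif(1, 0.4, 0.6)
          fill_aa(size, function(px, py) {
            d2 <- px^2 + py^2
            d2 < r^2 & d2 > r2^2
          })
        },
        rect = {
          w <- size * stats::runif(1, 0.24, 0.3); h <- w * stats::runif(1, 0.5, 1)
          fill_aa(size, function(px, py) abs(px) < w & abs(py) < h)
        },
        polygon = {
          k <- sample(3:8, 1L)
          r <- size * stats::runif(1, 0.27, 0.34)
          th <- 2 * pi * seq_len(k) / k + stats::runif(1, 0, 2 * pi)
          fill_aa(size, function(px, py)
            in_polygon(px, py, r * cos(th), r * sin(th)))
        },
        star = {
          k <- sample(4:7, 1L)
          r <- size * stats::runif(1, 0.27, 0.34)
          th <- pi * seq_len(2 * k) / k + stats::runif(1, 0, 2 * pi)
          rr <- rep(c(1.3 * r, 0.55 * r), k)
          fill_aa(size, function(px, py)
            in_polygon(px, py, rr * cos(th), rr * sin(th)))
        }
      )
    },
    blob = {
      # face stand-in: smooth radial-harmonic contour with interior features
      amp <- stats::runif(3, 0.03, 0.12)
      ph <- stats::runif(3, 0, 2 * pi)
      r0 <- size * stats::runif(1, 0.24, 0.3)
      eye_dx <- r0 * 0.38
      eye_dy <- r0 * 0.3
      eye_r <- r0 * stats::runif(1, 0.1, 0.16)
      mouth_w <- r0 * 0.5
      mouth_y <- -r0 * 0.4
      radius_at <- function(th) {
        r0 * (1 + amp[1] * cos(2 * th + ph[1]) + amp[2] * cos(3 * th + ph[2]) +
                amp[3] * cos(5 * th + ph[3]))
      }
      fill_aa(size, function(px, py) {
        th <- atan2(py, px)
        body <- px^2 + py^2 < radius_at(th)^2
        eyes <- ((px - eye_dx)^2 + (py - eye_dy)^2 < eye_r^2) |
          ((px + eye_dx)^2 + (py - eye_dy)^2 < eye_r^2)
        mouth <- abs(px) < mouth_w & abs(py - mouth_y) < r0 * 0.07
        body & !eyes & !mouth
      })
    },
    silhouette = {
      # fish stand-in: ellipse body + triangle tail + eye hole
      a <- size * stats::runif(1, 0.26, 0.33)    # body semi-major
      b <- a * stats::runif(1, 0.45, 0.6)
      tail_l <- a * stats::runif(1, 0.45, 0.65)
      eye_r <- b * 0.22
      fin <- stats::runif(1) < 0.5
      fill_aa(size, function(px, py) {
        body <- (px / a)^2 + (py / b)^2 < 1
        tail <- in_polygon(px, py,
                           c(-a * 0.9, -a * 0.9 - tail_l, -a * 0.9 - tail_l),
                           c(0, b * 0.8, -b * 0.8))
        eye <- (px - a * 0.55)^2 + (py - b * 0.25)^2 < eye_r^2
        dorsal <- fin & in_polygon(px, py,
                                   c(-a * 0.3, a * 0.1, -a * 0.05),
                                   c(b * 0.8, b * 0.8, b * 1.5))
        (body | tail | dorsal) & !eye
      })
    }
  )
}

# shift a raster by whole pixels, zero fill
shift_int <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  s <- nrow(img)
  out <- matrix(0, s, s)
  # +dx moves content right (columns), +dy up (rows decrease)
  src_c <- seq_len(s) - dx
  src_r <- seq_len(s) + dy
  ok_c <- src_c >= 1 & src_c <= s
  ok_r <- src_r >= 1 & src_r <= s
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

foreground_centroid <- function(img) {
  w <- sum(img)
  if (w == 0) return(c(NA_real_, NA_real_))
  co <- pixel_coords(nrow(img), ncol(img))
  c(sum(co$x * img) / w, sum(co$y * img) / w)   # center-relative, +y up
}

#' Render a synthetic test image
#'
#' @param recipe An [image_recipe()].
#' @return A `size x size` numeric matrix in `[0, 1]`, foreground centroid
#'   within 2 px of the image center, deterministic given the recipe seed.
#' @export
#' @examples
#' img <- render_image(image_recipe("shape", seed = 3))
#' dim(img)
render_image <- function(recipe) {
  stopifnot(inherits(recipe, "image_recipe"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  img <- render_kind(recipe$kind, recipe$size, recipe$seed)
  cen <- foreground_centroid(img)
  img <- shift_int(img, -round(cen[1]), -round(cen[2]))
  img
}

#' Rotate, scale and shift an image about its center
#'
#' Applies, in order: rotation about the image center, scaling about the
#' center, then a pixel shift; the result is resampled back onto the
#' original grid (inverse mapping), so it is cropped/padded implicitly.
#' Nearest-neighbour sampling is the default; an identity transform returns
#' the input bit-identically and 90-degree nearest rotations are exact grid
#' rotations.
#'
#' @param img Numeric matrix.
#' @param rotation Rotation angle in radians (counter-clockwise).
#' @param scale Scale factor (> 0).
#' @param shift Length-2 integer-ish vector, pixels `(dx, dy)`, +x right,
#'   +y up.
#' @param method `"nearest"` or `"bilinear"`.
#' @return Transformed matrix; attribute `degenerate = TRUE` is set if the
#'   result has no foreground pixel above 0.5.
#' @export
transform_image <- function(img, rotation = 0, scale = 1, shift = c(0, 0),
                            method = c("nearest", "bilinear")) {
  check_image(img)
  method <- match.arg(method)
  if (!is.numeric(scale) || scale <= 0) {
    rlang::abort("`scale` must be positive.", class = "ripplepond_bad_param")
  }
  nr <- nrow(img); nc <- ncol(img)
  co <- pixel_coords(nr, nc)
  # inverse map: undo shift, undo scale, undo rotation
  x <- (co$x - shift[1]) / scale
  y <- (co$y - shift[2]) / scale
  cr <- cos(rotation); sr <- sin(rotation)
  xs <- x * cr + y * sr
  ys <- -x * sr + y * cr
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  px <- xs + cx
  py <- cy - ys
  out <- matrix(0, nr, nc)
  if (method == "nearest") {
    ci <- round(px); ri <- round(py)
    ok <- ci >= 1 & ci <= nc & ri >= 1 & ri <= nr
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    ok <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
    out[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[cbind(y0[ok], x0[ok])] +
      fx[ok] * (1 - fy[ok]) * img[cbind(y0[ok], x0[ok] + 1)] +
      (1 - fx[ok]) * fy[ok] * img[cbind(y0[ok] + 1, x0[ok])] +
      fx[ok] * fy[ok] * img[cbind(y0[ok] + 1, x0[ok] + 1)]
  }
  if (!any(out > 0.5)) attr(out, "degenerate") <- TRUE
  out
}

#' Generate a reproducible mixed test set
#'
#' @param n Number of images.
#' @param mix Named proportions over the six kinds; must sum to 1. The
#'   default gives approximately equal numbers of each kind.
#' @param size Image side in pixels.
#' @param seed Master seed; each image gets a derived sub-seed.
#' @return A tibble with columns `id`, `kind`, `seed` and a list-column
#'   `image` of rendered matrices.
#' @export
#' @examples
#' ts <- make_test_set(6, seed = 1)
#' table(ts$kind)
make_test_set <- function(n,
                          mix = c(letter = 1, digit = 1, word = 1,
                                  shape = 1, blob = 1, silhouette = 1) / 6,
                          size = 200L, seed = 1L) {
  stopifnot(n >= 1L)
  if (abs(sum(mix) - 1) > 1e-8) {
    rlang::abort("`mix` proportions must sum to 1.", class = "ripplepond_bad_param")
  }
  kinds <- names(mix)
  counts <- floor(n * mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    counts[order(n * mix - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(n * mix - counts, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  kind_seq <- rep(kinds, times = counts)
  # derived per-image seeds, kept inside the 32-bit integer range
  sub_seed <- as.integer((as.double(seed) * 1000 + seq_len(n)) %%
                           .Machine$integer.max)
  tibble::tibble(
    id = seq_len(n),
    kind = kind_seq,
    seed = sub_seed,
    image = purrr::map2(kind_seq, sub_seed, function(k, s) {
      render_image(image_recipe(k, size = size, seed = s))
    })
  )
}
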