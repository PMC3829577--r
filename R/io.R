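#' Read a grayscale image (PNG or PGM)
#'
#' PNG files are read via the png package (8- or 16-bit, already scaled to
#' `[0, 1]`; color images are converted to luma by channel averaging).
#' PGM supports both the plain-text (`P2`) and binary (`P5`) variants,
#' rescaled by the stated maximum value.
#'
#' @param path File path; format chosen by extension.
#' @return A numeric matrix in `[0, 1]`, row 1 = image top.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "ripplepond_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3]))], c(1, 2), mean)
    return(img)
  }
  if (ext %in% c("pgm", "pnm")) {
    return(read_pgm(path))
  }
  rlang::abort(sprintf("unsupported image format: .%s", ext),
               class = "ripplepond_io_error")
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) {
    rlang::abort(sprintf("not a PGM file (magic '%s'): %s", magic, path),
                 class = "ripplepond_io_error")
  }
  # read header tokens (width, height, maxval), skipping comments
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) {
      rlang::abort(sprintf("truncated PGM header: %s", path),
                   class = "ripplepond_io_error")
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) {
        tokens <- c(tokens, buf)
        buf <- ""
      }
    } else {
      buf <- paste0(buf, ch)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  if (anyNA(c(w, h, mx)) || w < 1L || h < 1L || mx < 1L) {
    rlang::abort(sprintf("malformed PGM header (%s): %s",
                         paste(tokens, collapse = " "), path),
                 class = "ripplepond_io_error")
  }
  n <- w * h
  if (magic == "P5") {
    if (mx < 256L) {
      v <- as.integer(readBin(con, "raw", n))
    } else {
      v <- readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    v <- suppressWarnings(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(v) < n) {
    rlang::abort(sprintf("truncated PGM pixel data (%d of %d): %s",
                         length(v), n, path),
                 class = "ripplepond_io_error")
  }
  matrix(v / mx, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image (PNG or PGM)
#'
#' @param img Numeric matrix; values clamped to `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png` or `.pgm`,
#'   the latter written as plain-text `P2`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_image(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("pgm", "pnm")) {
    v <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    lines <- c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255",
               apply(v, 1L, paste, collapse = " "))
    writeLines(lines, path)
  } else {
    rlang::abort(sprintf("unsupported image format: .%s", ext),
                 class = "ripplepond_io_error")
  }
  invisible(path)
}

#' Write / read a temporal pattern
#'
#' CSV columns `step, value` plus a JSON sidecar (`<path>.json`) carrying
#' `m`, `dt`, the disc dimensions, the admission step and the shutter mode,
#' so a pattern round-trips losslessly.
#'
#' @param tp An `rpn_tp`.
#' @param path CSV path.
#' @return `write_tp()` returns `path` invisibly; `read_tp()` the `rpn_tp`.
#' @export
write_tp <- function(tp, path) {
  stopifnot(inherits(tp, "rpn_tp"))
  utils::write.csv(as.data.frame(tp), path, row.names = FALSE)
  jsonlite::write_json(
    list(m = attr(tp, "m"), dt = attr(tp, "dt"), arms = attr(tp, "arms"),
         per_arm = attr(tp, "per_arm"), t0 = attr(tp, "t0"),
         mode = attr(tp, "mode")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tp
#' @export
read_tp <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !identical(lines[1], "\"step\",\"value\"")) {
    rlang::abort(sprintf("line 1: expected header \"step\",\"value\" in %s", path),
                 class = "ripplepond_io_error")
  }
  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    rlang::abort(sprintf("line %d: malformed TP row in %s", bad[1] + 1L, path),
                 class = "ripplepond_io_error")
  }
  step <- as.integer(vapply(parts, `[`, character(1), 1L))
  value <- as.integer(vapply(parts, `[`, character(1), 2L))
  if (anyNA(step) || anyNA(value) || !identical(step, seq_along(step))) {
    rlang::abort(sprintf("non-contiguous or non-integer TP rows in %s", path),
                 class = "ripplepond_io_error")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(value) != meta$per_arm || sum(value) != meta$m) {
    rlang::abort(sprintf(
      "TP data inconsistent with sidecar (length %d vs N=%s; sum %d vs m=%s): %s",
      length(value), meta$per_arm, sum(value), meta$m, path),
      class = "ripplepond_io_error")
  }
  tp <- new_tp(value, meta$m, meta$arms, meta$per_arm, dt = meta$dt,
               t0 = meta$t0)
  attr(tp, "mode") <- meta$mode
  tp
}
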