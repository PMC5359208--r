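#' Read an 8-bit single-channel image
#'
#' Accepts 8-bit grayscale PNG or PGM (P2/P5). Colour or 16-bit inputs are
#' rejected with an explicit error rather than silently converted.
#'
#' @param path Path to a `.png` or `.pgm` file.
#' @return Integer matrix with values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L) {
      stop(sprintf("%s: only 8-bit images are supported (got %d-bit)",
                   path, info$bit.depth), call. = FALSE)
    }
    if (length(dim(a)) == 3L) {
      if (dim(a)[3L] > 1L) {
        stop(sprintf("%s: single-channel grayscale required (got %d channels)",
                     path, dim(a)[3L]), call. = FALSE)
      }
      a <- a[, , 1L]
    }
    img <- round(a * 255)
    storage.mode(img) <- "integer"
    img
  } else if (ext %in% c("pgm", "pnm")) {
    read_pgm(path)
  } else {
    stop(sprintf("%s: unsupported format '%s' (use PNG or PGM)", path, ext),
         call. = FALSE)
  }
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop(sprintf("%s: truncated PGM header", path), call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("^[ \t\r\n]$", ch)) {
        word <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("^[ \t\r\n#]$", ch)) break
          word <- paste0(word, ch)
        }
        return(word)
      }
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("%s: not a PGM file (magic '%s')", path, magic), call. = FALSE)
  }
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  if (is.na(w) || is.na(h) || is.na(maxv)) {
    stop(sprintf("%s: malformed PGM header", path), call. = FALSE)
  }
  if (maxv > 255L) {
    stop(sprintf("%s: only 8-bit PGM supported (maxval %d)", path, maxv),
         call. = FALSE)
  }
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    v <- integer(0)
    while (length(v) < w * h) {
      word <- tok()
      v <- c(v, as.integer(word))
    }
    v
  }
  if (length(vals) < w * h) stop(sprintf("%s: truncated PGM data", path), call. = FALSE)
  matrix(vals[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
}

#' Write images, masks and overlays
#'
#' `write_image()` writes an 8-bit grayscale PNG or PGM (P5); round-trips
#' through [read_image()] are lossless. `write_mask()` stores a binary mask
#' with foreground = 255. `write_overlay()` paints line pixels (e.g.
#' watershed lines) in red over the grayscale image, as PNG.
#'
#' @param path Output path; the extension selects the format.
#' @param img Integer matrix in 0..255.
#' @param mask,lines Logical masks.
#' @return Invisibly, the path written.
#' @export
write_image <- function(path, img) {
  img <- as_gray(img)
  if (max(img) > 255L) stop("`img` must be 8-bit (0-255)", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, target = path)
  } else if (ext %in% c("pgm", "pnm")) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
    writeBin(as.raw(as.integer(t(img))), con)
  } else {
    stop(sprintf("unsupported output format '%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(path, mask) {
  mask <- as_mask(mask)
  write_image(path, matrix((mask + 0L) * 255L, nrow(mask), ncol(mask)))
}

#' @rdname write_image
#' @export
read_mask <- function(path) {
  read_image(path) > 0L
}

#' @rdname write_image
#' @export
write_overlay <- function(path, img, lines) {
  img <- as_gray(img)
  lines <- as_mask(lines, "lines")
  check_same_shape(img, lines, "`img` and `lines`")
  g <- img / 255
  rgb <- array(0, dim = c(nrow(img), ncol(img), 3L))
  rgb[, , 1L] <- ifelse(lines, 1, g)
  rgb[, , 2L] <- ifelse(lines, 0, g)
  rgb[, , 3L] <- ifelse(lines, 0, g)
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Read detection parameters from a YAML or JSON config
#'
#' Recognised keys: `diff`, `th`, `h`, `n_pxls`, `min_pxls`, `max_pxls`;
#' absent keys keep their defaults, unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [detection_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    yaml::read_yaml(path)  # YAML is a JSON superset
  } else {
    stop(sprintf("unsupported config format '%s'", ext), call. = FALSE)
  }
  if (is.null(cfg)) cfg <- list()
  allowed <- c("diff", "th", "h", "n_pxls", "min_pxls", "max_pxls")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(detection_params, cfg)
}
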