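#' Detection parameters
#'
#' Parameters controlling the four-stage morphological microcalcification
#' detector. Defaults are the values established on a 20-ROI training set:
#' `diff` (intensity clip of stage 1), `th` (threshold applied to the
#' pyramid-level detector residue), `h` (height of the extended maximum),
#' `n_pxls` (longest directional chord, in pixels, a candidate region may
#' contain), `min_pxls`/`max_pxls` (inclusive area band, in pixels, of a
#' valid microcalcification region). The pyramid depth is fixed at 3 levels.
#'
#' @param diff Intensity shift of stage 1, `0 < diff < 255`. Default 21.
#' @param th Threshold on the detector residue, `>= 1`. Default 4.
#' @param h Extended-maximum height, `>= 1`. Default 5.
#' @param n_pxls Maximum directional chord length in pixels. Default 50.
#' @param min_pxls,max_pxls Area band in pixels. Defaults 10 and 70.
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(diff = 21L, th = 4L, h = 5L,
                             n_pxls = 50L, min_pxls = 10L, max_pxls = 70L) {
  p <- list(diff = as.integer(diff), th = as.integer(th), h = as.integer(h),
            n_pxls = as.integer(n_pxls), min_pxls = as.integer(min_pxls),
            max_pxls = as.integer(max_pxls), pyramid_levels = 3L)
  if (any(vapply(p, function(x) length(x) != 1L || is.na(x) || x <= 0L, TRUE))) {
    stop("all detection parameters must be positive scalars", call. = FALSE)
  }
  if (p$diff >= 255L) stop("`diff` must be < 255", call. = FALSE)
  if (p$min_pxls > p$max_pxls) stop("`min_pxls` must be <= `max_pxls`", call. = FALSE)
  structure(p, class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Microcalcification detection parameters:\n")
  cat(sprintf("  diff = %d, th = %d, h = %d, n_pxls = %d, area band = [%d, %d] px\n",
              x$diff, x$th, x$h, x$n_pxls, x$min_pxls, x$max_pxls))
  invisible(x)
}

check_params <- function(p) {
  if (!inherits(p, "detection_params")) {
    stop("`params` must come from detection_params()", call. = FALSE)
  }
  p
}

#' Stage 1: dark-end intensity clipping
#'
#' Shifting the image `diff` gray levels down (saturating at 0) and back up
#' removes all variance below `diff`; the closed form is the pointwise
#' maximum `max(img, diff)`. Small bright points in the darkest parts of the
#' ROI, which would otherwise mimic microcalcifications, are flattened away.
#'
#' @param img 8-bit integer matrix.
#' @param diff Intensity, `0 < diff < 255`.
#' @return Integer matrix with no value below `diff`.
#' @export
stage1_clip <- function(img, diff = 21L) {
  img <- as_gray(img)
  diff <- as.integer(diff)
  if (diff <= 0L || diff >= 255L) stop("`diff` must be in (0, 255)", call. = FALSE)
  pmax(img, diff)
}

#' Morphological pyramid
#'
#' Level 1 is the input; each next level applies the closing-opening filter
#' with the 3 x 3 square and keeps every second pixel (even 0-based indices)
#' per axis. Three levels are always returned.
#'
#' @param img Integer matrix, at least 8 x 8.
#' @return List of three integer matrices (levels 1, 2, 3).
#' @export
build_pyramid <- function(img) {
  img <- as_gray(img)
  if (nrow(img) < 8L || ncol(img) < 8L) {
    stop("image must be at least 8 x 8 to build a 3-level pyramid", call. = FALSE)
  }
  down <- function(x) {
    f <- co_filter(x)
    f[seq(1L, nrow(f), by = 2L), seq(1L, ncol(f), by = 2L), drop = FALSE]
  }
  l2 <- down(img)
  l3 <- down(l2)
  list(l1 = img, l2 = l2, l3 = l3)
}

#' Per-level detector residue and threshold
#'
#' Computes `T = I - min(opening(closing(I)), I)` with the 3 x 3 square and
#' thresholds it at `th`. The residue is non-negative and bounded by `I`; it
#' responds to small bright structures that the closing-opening surface
#' cannot follow.
#'
#' @param img Integer matrix (one pyramid level).
#' @param th Threshold intensity (default 4).
#' @return Logical mask of detector responses at this level's resolution.
#' @export
detect_level <- function(img, th = 4L) {
  img <- as_gray(img)
  resid <- img - pmin(opening(closing(img)), img)
  threshold_mask(resid, th)
}

#' Block upsampling of a level mask
#'
#' Replicates every pixel into a `scale` x `scale` block and crops to
#' `target_dim` (anchored at the origin) to restore the full-resolution
#' geometry of a pyramid-level detection mask.
#'
#' @param mask Logical mask at pyramid-level resolution.
#' @param scale 2 (level 2) or 4 (level 3).
#' @param target_dim Integer vector `c(nrow, ncol)` of the full image.
#' @return Logical mask of shape `target_dim`.
#' @export
upsample_mask <- function(mask, scale, target_dim) {
  mask <- as_mask(mask)
  if (!scale %in% c(2L, 4L)) stop("`scale` must be 2 or 4", call. = FALSE)
  target_dim <- as.integer(target_dim)
  if (nrow(mask) * scale < target_dim[1L] || ncol(mask) * scale < target_dim[2L]) {
    stop("mask too small to cover `target_dim` at this scale", call. = FALSE)
  }
  big <- kronecker(mask + 0L, matrix(1L, scale, scale)) > 0L
  big[seq_len(target_dim[1L]), seq_len(target_dim[2L]), drop = FALSE]
}

#' Stage 2: multiscale detection signals
#'
#' Runs the residue detector on pyramid levels 2 and 3 of the stage-1 output,
#' restores each mask to full resolution by block replication, and also
#' returns their OR. The per-level masks are kept separate because stage 4
#' reconstructs the extended-maximum support per level.
#'
#' @param img2 Stage-1 output image.
#' @param params [detection_params()].
#' @return List with logical masks `level2`, `level3`, `union`, all at full
#'   resolution.
#' @export
multiscale_signals <- function(img2, params = detection_params()) {
  img2 <- as_gray(img2)
  params <- check_params(params)
  pyr <- build_pyramid(img2)
  s2 <- detect_level(pyr$l2, params$th)
  s3 <- detect_level(pyr$l3, params$th)
  d <- dim(img2)
  u2 <- upsample_mask(s2, 2L, d)
  u3 <- upsample_mask(s3, 4L, d)
  list(level2 = u2, level3 = u3, union = u2 | u3)
}

#' Stage 3: extended-maximum support with large regions removed
#'
#' Computes the extended-maximum support `I_emax` (h-convexity residue of the
#' stage-1 image thresholded at 1), then removes every region inside which a
#' horizontal, vertical or diagonal chord longer than `n_pxls` pixels can be
#' drawn: eroding `I_emax` with four linear elements of length `n_pxls + 1`
#' leaves a non-empty marker exactly inside such regions, reconstruction
#' recovers them in full, and they are subtracted.
#'
#' @param img2 Stage-1 output image.
#' @param h Extended-maximum height (default 5).
#' @param n_pxls Longest admissible directional chord (default 50).
#' @return Logical mask of candidate bright regions.
#' @export
bright_regions <- function(img2, h = 5L, n_pxls = 50L) {
  img2 <- as_gray(img2)
  if (h < 1L) stop("`h` must be >= 1", call. = FALSE)
  if (n_pxls < 1L) stop("`n_pxls` must be >= 1", call. = FALSE)
  emax <- h_convexity(img2, h) >= 1L
  len <- as.integer(n_pxls) + 1L
  if (len %% 2L == 0L) len <- len + 1L  # line SEs are centred, odd length
  ei <- emax + 0L
  marker <- (cpp_erode(ei, se_line(len, "horizontal")$dr, se_line(len, "horizontal")$dc) > 0L) |
            (cpp_erode(ei, se_line(len, "vertical")$dr,   se_line(len, "vertical")$dc)   > 0L) |
            (cpp_erode(ei, se_line(len, "diag_left")$dr,  se_line(len, "diag_left")$dc)  > 0L) |
            (cpp_erode(ei, se_line(len, "diag_right")$dr, se_line(len, "diag_right")$dc) > 0L)
  large <- binary_reconstruct(marker, emax)
  emax & !large
}

#' Stage 4: microcalcification map assembly and cleaning
#'
#' For each pyramid level k in {2, 3}, the marker is the intersection of the
#' level's detection signal with the bright-region support; binary
#' reconstruction under the support recovers each candidate region hit by a
#' signal in full. The two reconstructions are OR-ed and cleaned in the fixed
#' order: border-touching regions removed, area band `[min_pxls, max_pxls]`
#' enforced, holes closed.
#'
#' @param bright Logical mask from [bright_regions()].
#' @param sig2,sig3 Full-resolution level masks from [multiscale_signals()].
#' @param params [detection_params()].
#' @return Logical microcalcification map.
#' @export
build_map <- function(bright, sig2, sig3, params = detection_params()) {
  bright <- as_mask(bright, "bright")
  sig2 <- as_mask(sig2, "sig2")
  sig3 <- as_mask(sig3, "sig3")
  params <- check_params(params)
  check_same_shape(bright, sig2, "`bright` and `sig2`")
  check_same_shape(bright, sig3, "`bright` and `sig3`")
  rec2 <- binary_reconstruct(bright & sig2, bright)
  rec3 <- binary_reconstruct(bright & sig3, bright)
  map <- rec2 | rec3
  map <- remove_border_objects(map)
  map <- area_filter(map, params$min_pxls, params$max_pxls, connectivity = 8L)
  fill_holes(map)
}

#' Morphological microcalcification detection
#'
#' End-to-end stage 1-4 detector: dark-end clipping, multiscale residue
#' detection on the morphological pyramid, extended-maximum support with
#' elongated regions removed, per-level reconstruction, and map cleaning.
#' Deterministic: identical input and parameters give a bit-identical map.
#'
#' @param img 8-bit integer matrix (values 0-255), at least 64 x 64.
#' @param params [detection_params()].
#' @return Logical microcalcification map ("map" of candidate regions).
#' @export
detect_mc <- function(img, params = detection_params()) {
  img <- as_gray(img)
  params <- check_params(params)
  if (max(img) > 255L) stop("`img` must be 8-bit (0-255)", call. = FALSE)
  if (nrow(img) < 64L || ncol(img) < 64L) {
    stop("ROI must be at least 64 x 64 pixels", call. = FALSE)
  }
  img2 <- stage1_clip(img, params$diff)
  sig <- multiscale_signals(img2, params)
  bright <- bright_regions(img2, params$h, params$n_pxls)
  build_map(bright, sig$level2, sig$level3, params)
}
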