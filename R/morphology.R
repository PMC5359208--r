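#' @useDynLib mammocalc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- internal validation helpers -------------------------------------------

as_gray <- function(img, arg = "img") {
  if (is.logical(img)) {
    storage.mode(img) <- "integer"
  }
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  if (!is.integer(img)) {
    if (any(img != round(img))) {
      stop(sprintf("`%s` must hold integer intensities", arg), call. = FALSE)
    }
    storage.mode(img) <- "integer"
  }
  if (any(img < 0L)) stop(sprintf("`%s` has negative intensities", arg), call. = FALSE)
  img
}

as_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1, 255))) {
      stop(sprintf("`%s` must be logical (or 0/255)", arg), call. = FALSE)
    }
    mask <- mask > 0
  }
  if (anyNA(mask)) stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  mask
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions", what), call. = FALSE)
  }
}

check_conn <- function(connectivity) {
  if (!(length(connectivity) == 1L && connectivity %in% c(4L, 8L))) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  as.integer(connectivity)
}

# ---- structuring elements ---------------------------------------------------

#' Flat structuring elements
#'
#' `se_square3()` is the 3 x 3 square used throughout the pipeline (filters,
#' gradient, marker dilation). `se_line()` builds a 1-pixel-thick centred
#' linear element of odd length along one of four directions; the detector
#' uses length `n_pxls + 1` lines to erode away regions containing a long
#' directional chord.
#'
#' A structuring element is represented by its integer offsets
#' (`dr`, `dc`) relative to the centre origin.
#'
#' @param length Odd positive integer, number of pixels along the line.
#' @param orientation One of `"horizontal"`, `"vertical"`, `"diag_left"`
#'   (top-left to bottom-right), `"diag_right"` (top-right to bottom-left).
#' @return An object of class `"mc_se"`.
#' @export
se_square3 <- function() {
  g <- expand.grid(dr = -1:1, dc = -1:1)
  structure(list(dr = as.integer(g$dr), dc = as.integer(g$dc), kind = "square3"),
            class = "mc_se")
}

#' @rdname se_square3
#' @export
se_line <- function(length,
                    orientation = c("horizontal", "vertical", "diag_left", "diag_right")) {
  orientation <- match.arg(orientation)
  if (length < 1L || length %% 2L == 0L) {
    stop("line structuring elements must have odd positive length", call. = FALSE)
  }
  half <- (as.integer(length) - 1L) %/% 2L
  k <- (-half):half
  off <- switch(orientation,
    horizontal = list(dr = rep(0L, length), dc = k),
    vertical   = list(dr = k, dc = rep(0L, length)),
    diag_left  = list(dr = k, dc = k),
    diag_right = list(dr = k, dc = -k)
  )
  structure(list(dr = as.integer(off$dr), dc = as.integer(off$dc),
                 kind = "line", orientation = orientation),
            class = "mc_se")
}

check_se <- function(se) {
  if (!inherits(se, "mc_se") || length(se$dr) == 0L) {
    stop("`se` must be a non-empty structuring element from se_square3()/se_line()",
         call. = FALSE)
  }
  se
}

# ---- primitives -------------------------------------------------------------

#' Flat grayscale erosion and dilation
#'
#' Minimum (erosion) / maximum (dilation, over the reflected element) filters
#' with border handling by edge replication, so a flat image is invariant and
#' no artificial responses appear at the ROI boundary.
#'
#' @param img Integer matrix of non-negative intensities.
#' @param se Structuring element from [se_square3()] or [se_line()].
#' @return Integer matrix of the same shape.
#' @export
erode <- function(img, se = se_square3()) {
  img <- as_gray(img)
  se <- check_se(se)
  cpp_erode(img, se$dr, se$dc)
}

#' @rdname erode
#' @export
dilate <- function(img, se = se_square3()) {
  img <- as_gray(img)
  se <- check_se(se)
  cpp_dilate(img, se$dr, se$dc)
}

#' Morphological opening, closing and the closing-opening filter
#'
#' `opening()` is erosion followed by dilation, `closing()` the reverse;
#' both are idempotent and bracket the identity
#' (`opening <= img <= closing` pointwise). `co_filter()` is closing followed
#' by opening with the 3 x 3 square: the alternating filter used to build the
#' morphological pyramid and to prepare the image for watershed segmentation.
#' It removes isolated bright spikes and dark pits of sub-element size.
#'
#' @inheritParams erode
#' @return Integer matrix of the same shape.
#' @export
opening <- function(img, se = se_square3()) {
  dilate(erode(img, se), se)
}

#' @rdname opening
#' @export
closing <- function(img, se = se_square3()) {
  erode(dilate(img, se), se)
}

#' @rdname opening
#' @export
co_filter <- function(img) {
  opening(closing(img, se_square3()), se_square3())
}

#' Morphological reconstruction by dilation / erosion
#'
#' `reconstruct_by_dilation()` iterates geodesic dilation of `marker` under
#' `mask` until stability: connected structures of `mask` touched by a
#' non-zero marker are recovered in full. A marker exceeding the mask is
#' clipped down to it. `reconstruct_by_erosion()` is the dual (marker above
#' the mask, geodesic erosion), used by minima imposition.
#'
#' @param marker,mask Integer matrices of identical shape.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix with `marker <= result <= mask`
#'   (reversed for the erosion variant).
#' @export
reconstruct_by_dilation <- function(marker, mask, connectivity = 8L) {
  marker <- as_gray(marker, "marker")
  mask <- as_gray(mask, "mask")
  check_same_shape(marker, mask, "`marker` and `mask`")
  connectivity <- check_conn(connectivity)
  marker <- pmin(marker, mask)
  cpp_reconstruct_dilation(marker, mask, connectivity)
}

#' @rdname reconstruct_by_dilation
#' @export
reconstruct_by_erosion <- function(marker, mask, connectivity = 8L) {
  marker <- as_gray(marker, "marker")
  mask <- as_gray(mask, "mask")
  check_same_shape(marker, mask, "`marker` and `mask`")
  connectivity <- check_conn(connectivity)
  marker <- pmax(marker, mask)
  top <- max(marker)
  top - cpp_reconstruct_dilation(top - marker, top - mask, connectivity)
}

#' h-convexity (h-maxima residue)
#'
#' Residue of the h-maxima transform:
#' `img - reconstruct_by_dilation(img - h, img)` with saturating subtraction
#' at 0. The result lies in `[0, h]` and is positive exactly on bright
#' structures standing above their spill level; thresholding it at 1 gives
#' the extended-maximum support used by the detector.
#'
#' @param img Integer matrix.
#' @param h Positive integer height parameter (pipeline default 5).
#' @return Integer matrix with values in `[0, h]`.
#' @export
h_convexity <- function(img, h) {
  img <- as_gray(img)
  if (length(h) != 1L || h < 1) stop("`h` must be >= 1", call. = FALSE)
  h <- as.integer(h)
  marker <- pmax(img - h, 0L)
  img - reconstruct_by_dilation(marker, img)
}

#' Fixed-level thresholding
#'
#' Foreground where `img >= t` (a pixel exactly at the threshold is kept).
#'
#' @param img Integer matrix.
#' @param t Threshold intensity.
#' @return Logical mask of the same shape.
#' @export
threshold_mask <- function(img, t) {
  img <- as_gray(img)
  img >= as.integer(t)
}

#' Regional minima
#'
#' Marks every connected iso-intensity plateau that has no strictly lower
#' neighbour under the chosen connectivity. A constant image is a single
#' regional minimum.
#'
#' @param img Integer matrix.
#' @param connectivity 4 or 8 (default 8, as used by the pipeline).
#' @return Logical mask.
#' @export
regional_minima <- function(img, connectivity = 8L) {
  img <- as_gray(img)
  cpp_regional_minima(img, check_conn(connectivity))
}

#' Minima imposition
#'
#' Forces the regional minima of `img` to coincide exactly with the connected
#' components of `marker`: with `f_m = 0` on the marker and a maximal
#' sentinel elsewhere, the result is the reconstruction by erosion of
#' `pmin(img + 1, f_m)` from `f_m`. Applied to the morphological gradient
#' before the final watershed, this is what suppresses oversegmentation.
#'
#' @param img Integer matrix.
#' @param marker Logical mask with at least one `TRUE` pixel.
#' @return Integer matrix whose 8-connected regional minima equal the
#'   components of `marker`.
#' @export
minima_imposition <- function(img, marker) {
  img <- as_gray(img)
  marker <- as_mask(marker, "marker")
  check_same_shape(img, marker, "`img` and `marker`")
  if (!any(marker)) stop("`marker` must contain at least one pixel", call. = FALSE)
  sentinel <- max(img) + 2L
  fm <- matrix(sentinel, nrow(img), ncol(img))
  fm[marker] <- 0L
  storage.mode(fm) <- "integer"
  g <- pmin(img + 1L, fm)
  reconstruct_by_erosion(fm, g, connectivity = 8L)
}

#' Watershed by immersion
#'
#' Vincent-Soille immersion watershed: basins are flooded from the regional
#' minima and labelled 1..k; pixels where two basins meet form explicit
#' watershed (divide) lines labelled 0. Flooding order is deterministic
#' (raster-order seeding, FIFO queues), so repeated runs are bit-identical.
#'
#' @param img Integer matrix (typically a gradient image).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix; 0 = watershed line, k >= 1 = basin k.
#' @export
watershed <- function(img, connectivity = 8L) {
  img <- as_gray(img)
  cpp_watershed(img, check_conn(connectivity))
}

#' Connected-component labelling
#'
#' @param mask Logical mask.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix, labels 1..k in raster-scan order of first
#'   contact, 0 on background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  mask <- as_mask(mask)
  cpp_label(mask, check_conn(connectivity))
}

#' Area filtering of binary components
#'
#' Keeps exactly the connected components whose pixel count lies in
#' `[min_px, max_px]`; the bounds themselves survive. This implements the
#' map-cleaning rule discarding regions smaller than `min_pxls` or larger
#' than `max_pxls`.
#'
#' @param mask Logical mask.
#' @param min_px,max_px Inclusive area bounds in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @return Logical mask.
#' @export
area_filter <- function(mask, min_px, max_px, connectivity = 8L) {
  mask <- as_mask(mask)
  if (min_px > max_px) stop("`min_px` must be <= `max_px`", call. = FALSE)
  lab <- cpp_label(mask, check_conn(connectivity))
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px & sizes <= max_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Hole filling and border-object removal
#'
#' `fill_holes()` turns background components not connected to the image
#' border (4-connected background, the standard dual of 8-connected
#' foreground) into foreground. `remove_border_objects()` deletes every
#' foreground component touching the image border, via binary reconstruction
#' from a border marker followed by subtraction.
#'
#' @param mask Logical mask.
#' @return Logical mask.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  bg <- !mask
  border <- border_mask(dim(mask))
  seed <- bg & border
  if (!any(seed)) return(mask | bg)  # whole border is foreground: fill all
  reach <- cpp_reconstruct_dilation(seed + 0L, bg + 0L, 4L) > 0L
  mask | (bg & !reach)
}

#' @rdname fill_holes
#' @export
remove_border_objects <- function(mask) {
  mask <- as_mask(mask)
  seed <- mask & border_mask(dim(mask))
  if (!any(seed)) return(mask)
  reach <- cpp_reconstruct_dilation(seed + 0L, mask + 0L, 8L) > 0L
  mask & !reach
}

border_mask <- function(d) {
  m <- matrix(FALSE, d[1L], d[2L])
  m[1L, ] <- TRUE
  m[d[1L], ] <- TRUE
  m[, 1L] <- TRUE
  m[, d[2L]] <- TRUE
  m
}

# Binary reconstruction convenience used by the detector (marker and mask
# logical; 8-connectivity).
binary_reconstruct <- function(marker, mask) {
  cpp_reconstruct_dilation((marker & mask) + 0L, mask + 0L, 8L) > 0L
}
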