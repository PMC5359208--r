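#' Watershed pre-processing of the ROI
#'
#' Closing-opening filtration followed by gray-level inversion
#' (`255 - co_filter(img)`): bright microcalcifications become dark basins
#' whose regional minima seed the marker-controlled watershed.
#'
#' @param img 8-bit integer matrix.
#' @return Integer matrix.
#' @export
prepare_image <- function(img) {
  img <- as_gray(img)
  if (max(img) > 255L) stop("`img` must be 8-bit (0-255)", call. = FALSE)
  255L - co_filter(img)
}

#' Internal marker
#'
#' Intersection of the 8-connected regional minima of the prepared
#' (filtered, inverted) image with the detection map: only minima that the
#' detector attributes to microcalcifications seed object basins.
#'
#' @param prepared Output of [prepare_image()].
#' @param map Logical detection map.
#' @return Logical mask.
#' @export
internal_marker <- function(prepared, map) {
  prepared <- as_gray(prepared, "prepared")
  map <- as_mask(map, "map")
  check_same_shape(prepared, map, "`prepared` and `map`")
  regional_minima(prepared, 8L) & map
}

#' External marker
#'
#' Watershed lines (0-labelled divide pixels) of the immersion watershed of
#' the prepared image: a connected network of background ridges that
#' separates all basins and never meets any regional minimum.
#'
#' @param prepared Output of [prepare_image()].
#' @return Logical mask.
#' @export
external_marker <- function(prepared) {
  prepared <- as_gray(prepared, "prepared")
  watershed(prepared, 8L) == 0L
}

#' Combine internal and external markers
#'
#' Internal-marker pixels must not touch the external marker: the external
#' marker is dilated with the 3 x 3 square and subtracted from the internal
#' one, then the trimmed internal marker is OR-ed with the (un-widened)
#' external marker.
#'
#' @param internal,external Logical masks of identical shape.
#' @return List of class `"marker_set"` with elements `internal` (trimmed),
#'   `external`, `combined`.
#' @export
combine_markers <- function(internal, external) {
  internal <- as_mask(internal, "internal")
  external <- as_mask(external, "external")
  check_same_shape(internal, external, "`internal` and `external`")
  widened <- dilate(external + 0L, se_square3()) > 0L
  internal2 <- internal & !widened
  combined <- internal2 | external
  if (!any(combined)) {
    stop(structure(class = c("mc_degenerate_marker", "error", "condition"),
                   list(message = "both markers empty: segmentation is vacuous",
                        call = sys.call(-1L))))
  }
  structure(list(internal = internal2, external = external, combined = combined),
            class = "marker_set")
}

#' Marker-controlled watershed segmentation of microcalcifications
#'
#' Runs the full shape-extraction chain: prepare the image, build internal
#' and external markers, compute the morphological gradient
#' (`dilate - erode`, 3 x 3 square), impose the combined marker as the
#' gradient's only regional minima, and flood the modified gradient with the
#' immersion watershed. Basins containing internal-marker pixels are the
#' segmented microcalcifications; the remaining basins are background.
#'
#' When the map is empty, or no regional minimum survives inside it, an
#' empty result with `n_objects = 0` is returned rather than an error.
#'
#' @param img 8-bit integer matrix.
#' @param map Logical detection map (e.g. from [detect_mc()]); if `NULL`,
#'   detection is run first with `params`.
#' @param params [detection_params()], used only when `map` is `NULL`.
#' @return Object of class `"mc_segmentation"`: list with `object_mask`
#'   (logical), `watershed_lines` (logical), `labels` (full watershed label
#'   image), `objects` (label image of segmented objects only, renumbered
#'   1..n), `markers` (the `marker_set`, or `NULL` for empty results) and
#'   `n_objects`.
#' @export
segment_mc <- function(img, map = NULL, params = detection_params()) {
  img <- as_gray(img)
  if (is.null(map)) map <- detect_mc(img, params)
  map <- as_mask(map, "map")
  check_same_shape(img, map, "`img` and `map`")

  empty_result <- function() {
    z <- matrix(FALSE, nrow(img), ncol(img))
    zl <- matrix(0L, nrow(img), ncol(img))
    structure(list(object_mask = z, watershed_lines = z, labels = zl,
                   objects = zl, markers = NULL, n_objects = 0L),
              class = "mc_segmentation")
  }

  prepared <- prepare_image(img)
  internal <- internal_marker(prepared, map)
  if (!any(internal)) return(empty_result())
  external <- external_marker(prepared)
  markers <- combine_markers(internal, external)
  if (!any(markers$internal)) return(empty_result())

  grad <- dilate(prepared, se_square3()) - erode(prepared, se_square3())
  grad2 <- minima_imposition(grad, markers$combined)
  labels <- watershed(grad2, 8L)

  obj_labels <- sort(unique(labels[markers$internal & labels > 0L]))
  object_mask <- matrix(labels %in% obj_labels, nrow(img), ncol(img))
  objects <- matrix(match(labels, obj_labels, nomatch = 0L), nrow(img), ncol(img))
  structure(list(object_mask = object_mask,
                 watershed_lines = labels == 0L,
                 labels = labels,
                 objects = objects,
                 markers = markers,
                 n_objects = length(obj_labels)),
            class = "mc_segmentation")
}

#' @export
print.mc_segmentation <- function(x, ...) {
  cat(sprintf("Microcalcification segmentation: %d object(s), %d object pixels, %d line pixels\n",
              x$n_objects, sum(x$object_mask), sum(x$watershed_lines)))
  invisible(x)
}
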