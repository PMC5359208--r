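#' Pixel-overlap indices between a segmentation and an expert tracing
#'
#' For a computed region set M and an expert region set E (binary masks),
#' computes the similarity index `SI = 2|M n E| / (|M| + |E|)`, the overlap
#' fraction `OF = |M n E| / |E|`, the overlap value (Jaccard)
#' `OV = |M n E| / |M u E|`, and the extra fraction `EF = |M n !E| / |E|`.
#' SI, OF, OV lie in [0, 1]; EF is non-negative and may exceed 1.
#'
#' @param m Logical mask of computed regions (M).
#' @param e Logical mask of expert-traced regions (E); must be non-empty.
#' @return A one-row data frame with columns `si`, `of`, `ov`, `ef`, `n_m`,
#'   `n_e`, `n_inter`.
#' @export
overlap_indices <- function(m, e) {
  m <- as_mask(m, "m")
  e <- as_mask(e, "e")
  check_same_shape(m, e, "`m` and `e`")
  n_e <- sum(e)
  if (n_e == 0L) stop("`e` must contain at least one pixel", call. = FALSE)
  n_m <- sum(m)
  n_inter <- sum(m & e)
  data.frame(
    si = 2 * n_inter / (n_m + n_e),
    of = n_inter / n_e,
    ov = n_inter / sum(m | e),
    ef = sum(m & !e) / n_e,
    n_m = n_m, n_e = n_e, n_inter = n_inter
  )
}

#' Object-level TP/FP/FN classification
#'
#' Matches segmented objects to ground-truth objects one-to-one, greedily by
#' decreasing pixel overlap; a pair is accepted when the overlap covers at
#' least `tau` of the truth object's area. Matched objects are true
#' positives; unmatched segmented objects are false positives regardless of
#' whether they fall inside or outside the ground-truth area; unmatched
#' truth objects are false negatives. `fpi` (false positives in this image)
#' equals `fp`.
#'
#' @param segmented Integer label image of segmented objects (0 background).
#' @param truth_objects Integer label image of true objects (0 background).
#' @param gta Optional logical ground-truth-area mask (carried for
#'   reporting; both FP rules collapse to the same count).
#' @param tau Required overlap as a fraction of the truth object's area,
#'   in (0, 1]. Default 0.5.
#' @return A one-row data frame with `tp`, `fp`, `fn`, `fpi`, `sensitivity`
#'   (`NA` if there are no truth objects).
#' @export
classify_objects <- function(segmented, truth_objects, gta = NULL, tau = 0.5) {
  if (!is.matrix(segmented) || !is.matrix(truth_objects)) {
    stop("`segmented` and `truth_objects` must be label matrices", call. = FALSE)
  }
  check_same_shape(segmented, truth_objects, "`segmented` and `truth_objects`")
  if (!is.null(gta)) {
    gta <- as_mask(gta, "gta")
    check_same_shape(segmented, gta, "`segmented` and `gta`")
  }
  if (length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1) {
    stop("`tau` must lie in (0, 1]", call. = FALSE)
  }
  seg_ids <- sort(unique(segmented[segmented > 0L]))
  tru_ids <- sort(unique(truth_objects[truth_objects > 0L]))
  n_seg <- length(seg_ids)
  n_tru <- length(tru_ids)

  tp <- 0L
  if (n_seg > 0L && n_tru > 0L) {
    both <- segmented > 0L & truth_objects > 0L
    if (any(both)) {
      ov <- as.data.frame(table(seg = segmented[both], tru = truth_objects[both]),
                          stringsAsFactors = FALSE)
      ov <- ov[ov$Freq > 0L, , drop = FALSE]
      ov$seg <- as.integer(ov$seg)
      ov$tru <- as.integer(ov$tru)
      tru_area <- tabulate(truth_objects[truth_objects > 0L],
                           nbins = max(tru_ids))
      ov <- ov[ov$Freq >= tau * tru_area[ov$tru], , drop = FALSE]
      # greedy one-to-one matching by decreasing overlap; deterministic
      # tie-break on (truth id, segment id)
      ov <- ov[order(-ov$Freq, ov$tru, ov$seg), , drop = FALSE]
      seg_used <- integer(0)
      tru_used <- integer(0)
      for (i in seq_len(nrow(ov))) {
        if (ov$seg[i] %in% seg_used || ov$tru[i] %in% tru_used) next
        seg_used <- c(seg_used, ov$seg[i])
        tru_used <- c(tru_used, ov$tru[i])
        tp <- tp + 1L
      }
    }
  }
  fp <- n_seg - tp
  fn <- n_tru - tp
  data.frame(tp = tp, fp = fp, fn = fn, fpi = fp,
             sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_)
}

#' Per-microcalcification sensitivity
#'
#' `TP / (TP + FN)`. When `decimals` is given, the printed-style value is
#' returned by truncating (not rounding) to that many decimal digits —
#' matching the convention under which 9 of 11 detected reads 0.81 and 2 of
#' 3 reads 0.66.
#'
#' @param tp,fn Non-negative counts with `tp + fn > 0`.
#' @param decimals Optional number of decimal digits to truncate to.
#' @return Numeric scalar.
#' @export
sensitivity <- function(tp, fn, decimals = NULL) {
  if (tp < 0 || fn < 0 || tp + fn <= 0) {
    stop("`tp + fn` must be positive", call. = FALSE)
  }
  s <- tp / (tp + fn)
  if (!is.null(decimals)) {
    f <- 10^as.integer(decimals)
    s <- trunc(s * f) / f
  }
  s
}

#' Summary of per-ROI evaluation results
#'
#' Mean, standard deviation, minimum and maximum of each overlap index, plus
#' (when detection counts are present) sensitivity statistics grouped by the
#' number of false positives per image.
#'
#' @param per_roi Data frame with one row per ROI, containing some of the
#'   columns `si`, `of`, `ov`, `ef`, `sensitivity`, `fpi`.
#' @return List with `indices` (one row per index: mean/sd/min/max) and,
#'   if `fpi` is present, `by_fpi` (ROI counts and sensitivity statistics
#'   per FPI value).
#' @export
summarize_eval <- function(per_roi) {
  if (!is.data.frame(per_roi) || nrow(per_roi) == 0L) {
    stop("`per_roi` must be a non-empty data frame", call. = FALSE)
  }
  idx_cols <- intersect(c("si", "of", "ov", "ef", "sensitivity"), names(per_roi))
  stats <- lapply(idx_cols, function(col) {
    v <- per_roi[[col]]
    v <- v[!is.na(v)]
    data.frame(index = col, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v))
  })
  out <- list(indices = do.call(rbind, stats))
  if ("fpi" %in% names(per_roi) && "sensitivity" %in% names(per_roi)) {
    sp <- split(per_roi$sensitivity, per_roi$fpi)
    out$by_fpi <- do.call(rbind, lapply(names(sp), function(k) {
      v <- sp[[k]][!is.na(sp[[k]])]
      data.frame(fpi = as.integer(k), n_rois = length(sp[[k]]),
                 mean_sensitivity = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_)
    }))
  }
  out
}

#' Evaluate a segmentation against phantom (or expert) truth
#'
#' Convenience wrapper combining [overlap_indices()] on the pixel masks with
#' [classify_objects()] on the object label images.
#'
#' @param seg An `"mc_segmentation"` result.
#' @param truth A phantom truth list (from [generate_phantom()]) or any list
#'   with elements `calc_mask`, `calc_labels` and optionally `gta`.
#' @param tau Overlap threshold for object matching (default 0.5).
#' @return One-row data frame with overlap indices and detection counts.
#' @export
evaluate_segmentation <- function(seg, truth, tau = 0.5) {
  if (!inherits(seg, "mc_segmentation")) {
    stop("`seg` must come from segment_mc()", call. = FALSE)
  }
  idx <- if (sum(truth$calc_mask) > 0L) {
    overlap_indices(seg$object_mask, truth$calc_mask)
  } else {
    data.frame(si = NA_real_, of = NA_real_, ov = NA_real_, ef = NA_real_,
               n_m = sum(seg$object_mask), n_e = 0L, n_inter = 0L)
  }
  cnt <- classify_objects(seg$objects, truth$calc_labels,
                          gta = truth$gta, tau = tau)
  cbind(idx, cnt)
}
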