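#' Match detections against ground-truth boxes
#'
#' A detection is a true positive when it shares strictly positive volume
#' with at least one truth box; a truth is detected when at least one
#' detection overlaps it.  One detection may validate several truths and
#' vice versa.  Overlap is axis-aligned box intersection in mm.
#'
#' @param dets an `mcc_detections` table (or any data frame with
#'   `xmin_mm..zmax_mm` bounds).
#' @param truths an `mcc_annotations` data frame (possibly empty).
#' @return a `match_result` list: `det_label` (`"TP"`/`"FP"` per detection),
#'   `truth_detected` (logical per truth), `overlap_mm3` (detections x
#'   truths matrix), `n_tp`, `n_fp`, and `sensitivity` (`NA` when there are
#'   no truths).
#' @export
match_detections <- function(dets, truths) {
  nd <- nrow(dets); nt <- nrow(truths)
  ov <- matrix(0, nrow = nd, ncol = nt)
  if (nd > 0 && nt > 0) {
    for (i in seq_len(nd)) {
      dx <- pmin(dets$xmax_mm[i], truths$xmax_mm) -
            pmax(dets$xmin_mm[i], truths$xmin_mm)
      dy <- pmin(dets$ymax_mm[i], truths$ymax_mm) -
            pmax(dets$ymin_mm[i], truths$ymin_mm)
      dz <- pmin(dets$zmax_mm[i], truths$zmax_mm) -
            pmax(dets$zmin_mm[i], truths$zmin_mm)
      ov[i, ] <- pmax(dx, 0) * pmax(dy, 0) * pmax(dz, 0)
    }
  }
  is_tp <- if (nt > 0) apply(ov > 0, 1, any) else rep(FALSE, nd)
  truth_hit <- if (nd > 0) apply(ov > 0, 2, any) else rep(FALSE, nt)
  structure(list(det_label = ifelse(is_tp, "TP", "FP"),
                 truth_detected = as.logical(truth_hit),
                 overlap_mm3 = ov,
                 n_tp = sum(is_tp), n_fp = sum(!is_tp),
                 sensitivity = if (nt > 0) sum(truth_hit) / nt else NA_real_),
            class = "match_result")
}

#' View-based pooled metrics over a set of volumes
#'
#' Sensitivity pooled over all truths across volumes; false positives
#' averaged per volume, with separate means for truth-containing and
#' truth-free volumes.
#'
#' @param matches a list of `match_result`s, one per volume.
#' @return a list with `sensitivity` (`NA` if no truths anywhere),
#'   `fp_per_volume`, `fp_per_volume_with_truth`,
#'   `fp_per_volume_without_truth`, `n_volumes`, `n_truths`.
#' @export
case_metrics <- function(matches) {
  if (length(matches) == 0L)
    stop("`matches` must contain at least one volume", call. = FALSE)
  n_truths <- vapply(matches, function(m) length(m$truth_detected), integer(1))
  n_hit <- vapply(matches, function(m) sum(m$truth_detected), integer(1))
  n_fp <- vapply(matches, function(m) m$n_fp, integer(1))
  has_truth <- n_truths > 0
  list(sensitivity = if (sum(n_truths) > 0) sum(n_hit) / sum(n_truths)
                     else NA_real_,
       fp_per_volume = mean(n_fp),
       fp_per_volume_with_truth = if (any(has_truth)) mean(n_fp[has_truth])
                                  else NA_real_,
       fp_per_volume_without_truth = if (any(!has_truth)) mean(n_fp[!has_truth])
                                     else NA_real_,
       n_volumes = length(matches), n_truths = sum(n_truths))
}

#' Free-response ROC curve over a scored detection batch
#'
#' Sweeps a score threshold over the pooled distinct detection scores (plus
#' a sentinel above the maximum, giving the empty-detection endpoint at 0
#' FPs), keeps detections with `score >= threshold` at each step, and pools
#' view-based metrics over the batch.
#'
#' @param dets_per_volume list of detection tables, one per volume (each
#'   with a finite `score` column).
#' @param truths_per_volume list of `mcc_annotations`, one per volume.
#' @return an `froc_result` list with `points` (data frame `threshold`,
#'   `fp_per_volume`, `sensitivity`, sorted by FPs ascending) and
#'   `n_volumes`.
#' @export
froc_curve <- function(dets_per_volume, truths_per_volume) {
  stopifnot(length(dets_per_volume) == length(truths_per_volume))
  scores <- unlist(lapply(dets_per_volume, function(d)
    if (nrow(d)) d$score else numeric()))
  if (length(scores) && any(!is.finite(scores)))
    stop("every detection must carry a finite score", call. = FALSE)
  thr <- sort(unique(c(scores, if (length(scores)) max(scores) + 1 else 0)),
              decreasing = FALSE)
  pts <- lapply(thr, function(t) {
    matches <- mapply(function(d, g) {
      keep <- if (nrow(d)) d[d$score >= t, , drop = FALSE] else d
      match_detections(keep, g)
    }, dets_per_volume, truths_per_volume, SIMPLIFY = FALSE)
    cm <- case_metrics(matches)
    data.frame(threshold = t, fp_per_volume = cm$fp_per_volume,
               sensitivity = cm$sensitivity)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[order(pts$fp_per_volume, pts$sensitivity), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, n_volumes = length(dets_per_volume)),
            class = "froc_result")
}

#' Normalized partial area under the FROC curve
#'
#' Trapezoidal area of sensitivity versus mean FPs per volume over
#' `[0, fp_max]`, with the curve extended rightward at its last sensitivity
#' and divided by `fp_max`, so a perfect detector scores 1.  Where several
#' operating points share an FP rate, the best sensitivity is used.
#'
#' @param fr an `froc_result` (or a data frame with `fp_per_volume`,
#'   `sensitivity`).
#' @param fp_max normalization bound in FPs per volume (must be positive).
#' @return area in `[0, 1]`.
#' @export
froc_area_normalized <- function(fr, fp_max) {
  if (!is.numeric(fp_max) || length(fp_max) != 1 || fp_max <= 0)
    stop("`fp_max` must be a positive scalar", call. = FALSE)
  pts <- if (inherits(fr, "froc_result")) fr$points else as.data.frame(fr)
  pts <- pts[is.finite(pts$sensitivity), , drop = FALSE]
  if (nrow(pts) == 0L) return(0)
  # best sensitivity per distinct FP rate, sorted ascending
  agg <- stats::aggregate(sensitivity ~ fp_per_volume, data = pts, FUN = max)
  x <- agg$fp_per_volume; y <- agg$sensitivity
  o <- order(x); x <- x[o]; y <- y[o]
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) } # nothing attainable below first point
  if (x[length(x)] < fp_max) { x <- c(x, fp_max); y <- c(y, y[length(y)]) }
  keep <- x <= fp_max
  if (any(!keep)) {
    # interpolate the curve at fp_max before truncating
    i <- which(!keep)[1]
    y_at <- y[i - 1] + (y[i] - y[i - 1]) * (fp_max - x[i - 1]) / (x[i] - x[i - 1])
    x <- c(x[keep], fp_max); y <- c(y[keep], y_at)
  }
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / fp_max
}

#' Plot an FROC curve
#'
#' @param x an `froc_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.froc_result <- function(x, ...) {
  pts <- x$points[is.finite(x$points$sensitivity), , drop = FALSE]
  graphics::plot(pts$fp_per_volume, pts$sensitivity, type = "b", pch = 16,
                 xlab = "Mean false positives per volume",
                 ylab = "Sensitivity", ylim = c(0, 1), ...)
  invisible(x)
}

#' Write FROC operating points as delimited text
#'
#' @param fr an `froc_result`.
#' @param path output CSV path.
#' @export
write_froc <- function(fr, path) {
  write.csv(fr$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
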