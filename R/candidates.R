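#' 3D connected-component labeling of a binary mask
#'
#' Partitions the foreground of a binary volume into maximal connected sets
#' under 6-, 18- or 26-connectivity.  Components are labeled in ascending
#' order of their first voxel's raster (column-major linear) index, so the
#' result is deterministic and independent of how the mask was produced.
#'
#' @param mask a [dbt_volume()] with logical or 0/1 data.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @param source optional [dbt_volume()] on the same grid whose values fill
#'   each object's `peak_value`; defaults to the mask itself.
#' @return a `labeled_objects` data frame with columns `label`, `x_mm`,
#'   `y_mm`, `z_mm` (centroid), `voxel_count`, `volume_mm3`, `peak_value`,
#'   and a list column `voxels` of 1-based `(i, j, k)` index matrices.
#' @export
connected_components <- function(mask, connectivity = 26L, source = NULL) {
  stopifnot(inherits(mask, "dbt_volume"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (!is.null(source)) stopifnot_same_grid(mask, source, "mask and source")
  d <- dim(mask$data)
  m <- as.integer(as.vector(mask$data) != 0)
  lab <- cpp_label3d(m, as.integer(d), connectivity)
  fg <- which(lab > 0L)
  src <- if (is.null(source)) mask else source
  make_labeled_objects(lab, fg, d, src$data, mask$spacing, mask$origin,
                       connectivity)
}

make_labeled_objects <- function(lab, fg, d, source_data, spacing, origin,
                                 connectivity) {
  if (length(fg) == 0L) {
    out <- data.frame(label = integer(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), voxel_count = integer(),
                      volume_mm3 = numeric(), peak_value = numeric())
    out$voxels <- list()
  } else {
    grp <- lab[fg]
    ord <- order(grp, fg)
    fg <- fg[ord]; grp <- grp[ord]
    idx <- arrayInd(fg, d)
    splits <- split(seq_along(fg), grp)
    labels <- as.integer(names(splits))
    vox_list <- lapply(splits, function(s) idx[s, , drop = FALSE])
    counts <- vapply(vox_list, nrow, integer(1))
    cent <- t(vapply(vox_list, function(m)
      origin + (colMeans(m) - 1) * spacing, numeric(3)))
    peaks <- vapply(splits, function(s) max(source_data[fg[s]]), numeric(1))
    out <- data.frame(label = labels, x_mm = cent[, 1], y_mm = cent[, 2],
                      z_mm = cent[, 3], voxel_count = counts,
                      volume_mm3 = counts * prod(spacing),
                      peak_value = peaks)
    out$voxels <- unname(vox_list)
    rownames(out) <- NULL
  }
  attr(out, "spacing") <- spacing
  attr(out, "origin") <- origin
  attr(out, "connectivity") <- connectivity
  class(out) <- c("labeled_objects", "data.frame")
  out
}

#' Find a binarization threshold producing a target component count
#'
#' Searches for a grey-level threshold `t` such that `{field > t}` has about
#' `target_count` connected components, by bisection over the field's value
#' range.  Component counts are not monotone in `t` (lowering the threshold
#' merges components as well as adding them), so the search tracks the best
#' threshold seen and falls back to the nearest achievable count, preferring
#' the higher threshold on ties, when the count function jumps over the
#' tolerance window.
#'
#' @param field a [dbt_volume()].
#' @param target_count desired number of components (reference: ~500 seed
#'   objects for a clinical DBT view).
#' @param connectivity passed to the labeling (default 26).
#' @param tolerance acceptable relative deviation from `target_count`.
#' @param max_iter bisection iteration bound.
#' @return the threshold, with attribute `achieved_count`.
#' @export
threshold_for_count <- function(field, target_count, connectivity = 26L,
                                tolerance = 0.1, max_iter = 60L) {
  stopifnot(inherits(field, "dbt_volume"))
  if (!is.numeric(target_count) || target_count < 1)
    stop("`target_count` must be a positive integer", call. = FALSE)
  if (tolerance <= 0 || tolerance >= 1)
    stop("`tolerance` must lie in (0, 1)", call. = FALSE)
  lo <- min(field$data); hi <- max(field$data)
  if (hi <= lo)
    stop("field is constant: no valid threshold exists", call. = FALSE)
  d <- as.integer(dim(field$data))
  count_at <- function(t)
    cpp_count_components(as.integer(as.vector(field$data) > t), d,
                         as.integer(connectivity))
  best_t <- NA_real_; best_count <- NA_integer_
  consider <- function(t, n) {
    if (is.na(best_t) ||
        abs(n - target_count) < abs(best_count - target_count) ||
        (abs(n - target_count) == abs(best_count - target_count) && t > best_t)) {
      best_t <<- t; best_count <<- n
    }
  }
  window <- tolerance * target_count
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    n <- count_at(mid)
    consider(mid, n)
    if (abs(n - target_count) <= window) break
    if (n > target_count) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(abs(hi), abs(lo), 1)) break
  }
  if (abs(best_count - target_count) > window)
    warning(sprintf(
      "threshold search reached count %d (target %d +/- %.0f); using nearest",
      best_count, as.integer(target_count), window))
  structure(best_t, achieved_count = best_count)
}

#' Extract cluster seed objects from the MOR image
#'
#' Thresholds the multiscale object-type response at a level chosen to yield
#' about `target_count` connected components (the candidate cluster centers)
#' and labels them, sorted by descending peak response.
#'
#' @param mor the MOR [dbt_volume()] from [compute_mor()].
#' @param target_count desired seed count (default 500).
#' @inheritParams threshold_for_count
#' @return a `labeled_objects` data frame sorted by descending `peak_value`,
#'   with attribute `threshold`.
#' @export
extract_seed_objects <- function(mor, target_count = 500L,
                                 connectivity = 26L, tolerance = 0.1) {
  thr <- threshold_for_count(mor, target_count, connectivity, tolerance)
  mask <- dbt_volume(array(as.numeric(mor$data > as.numeric(thr)),
                           dim = dim(mor$data)),
                     spacing = mor$spacing, origin = mor$origin)
  obj <- connected_components(mask, connectivity, source = mor)
  ord <- order(-obj$peak_value, obj$label)
  obj <- obj[ord, , drop = FALSE]
  rownames(obj) <- NULL
  class(obj) <- c("labeled_objects", "data.frame")
  attr(obj, "spacing") <- mor$spacing
  attr(obj, "origin") <- mor$origin
  attr(obj, "connectivity") <- as.integer(connectivity)
  attr(obj, "threshold") <- as.numeric(thr)
  obj
}

#' Local noise-to-mean statistic of the SNR-enhanced image
#'
#' At every voxel, the grey-level variance over a local neighborhood of the
#' SNR-enhanced field divided by the local mean (plus a tiny floor guarding
#' the division).  Voxels whose local mean is not positive map to 0.  The
#' conventional `sd / mean` form is available via `form`.
#'
#' @param snr the band-pass SNR [dbt_volume()] from [snr_enhance()].
#' @param window odd `(nx, ny, nz)` neighborhood in voxels; the default
#'   `c(9, 9, 3)` spans about 0.9 x 0.9 x 3 mm at the reference geometry.
#' @param form `"variance_over_mean"` (default) or `"std_over_mean"`.
#' @return a non-negative [dbt_volume()].
#' @export
compute_snr3d <- function(snr, window = c(9L, 9L, 3L),
                          form = c("variance_over_mean", "std_over_mean")) {
  stopifnot(inherits(snr, "dbt_volume"))
  form <- match.arg(form)
  window <- as.integer(window)
  if (length(window) != 3L || any(window < 1L) || any(window %% 2L == 0L))
    stop("`window` must be three odd positive integers", call. = FALSE)
  d <- dim(snr$data)
  if (any(window > d))
    stop("`window` does not fit inside the volume", call. = FALSE)
  box <- function(arr, axis, m) {
    if (m == 1L) return(arr)
    conv1d_vol(arr, axis, rep(1 / m, m))
  }
  box3 <- function(arr) box(box(box(arr, 1, window[1]), 2, window[2]),
                            3, window[3])
  mu <- box3(snr$data)
  v2 <- pmax(box3(snr$data^2) - mu^2, 0)
  eps <- 1e-12 * max(snr$data, 0)
  num <- if (form == "variance_over_mean") v2 else sqrt(v2)
  out <- ifelse(mu > 0, num / (mu + eps), 0)
  dbt_volume(array(out, dim = d), spacing = snr$spacing, origin = snr$origin)
}

#' Extract individual MC candidates from the SNR3D image
#'
#' Binarizes the SNR3D field at a fixed threshold (default 3.2) and labels
#' the connected components as individual microcalcification candidates.
#' When the fixed threshold yields a count far from `fallback_target`
#' (outside 0.2x--5x) a warning is logged, but the threshold is not silently
#' changed; set `count_targeted = TRUE` to search for a threshold producing
#' about `fallback_target` candidates instead.
#'
#' @param snr3d [dbt_volume()] from [compute_snr3d()].
#' @param snr_threshold fixed binarization level (default 3.2).
#' @param fallback_target expected candidate count scale (default 5000 for a
#'   clinical view; synthetic phantoms sit far below this).
#' @param count_targeted use [threshold_for_count()] instead of the fixed
#'   threshold.
#' @inheritParams threshold_for_count
#' @return a `labeled_objects` data frame with attribute `threshold`.
#' @export
extract_mc_candidates <- function(snr3d, snr_threshold = 3.2,
                                  fallback_target = 5000L,
                                  count_targeted = FALSE,
                                  connectivity = 26L, tolerance = 0.1) {
  stopifnot(inherits(snr3d, "dbt_volume"))
  if (count_targeted) {
    thr <- as.numeric(threshold_for_count(snr3d, fallback_target,
                                          connectivity, tolerance))
  } else {
    thr <- snr_threshold
  }
  mask <- dbt_volume(array(as.numeric(snr3d$data > thr), dim = dim(snr3d$data)),
                     spacing = snr3d$spacing, origin = snr3d$origin)
  obj <- connected_components(mask, connectivity, source = snr3d)
  if (!count_targeted) {
    n <- nrow(obj)
    if (n > 0 && (n < 0.2 * fallback_target || n > 5 * fallback_target))
      message(sprintf(
        "fixed SNR threshold %.2f yields %d MC candidates (expected scale ~%d)",
        snr_threshold, n, as.integer(fallback_target)))
  }
  attr(obj, "threshold") <- thr
  obj
}

#' Associate MC candidates with cluster seeds within a radius
#'
#' One cluster candidate per seed: an MC candidate is a member when its
#' centroid lies within `radius_mm` (Euclidean, in physical mm) of the seed
#' centroid; a candidate may belong to several clusters.  Members are sorted
#' by distance, then label.  `member_voxel_count` counts the member voxels
#' whose physical centers fall within the radius of the seed centroid — the
#' quantity thresholded by the first false-positive rule — and doubles as
#' the cluster score.
#'
#' @param seeds,mcs `labeled_objects` tables on the same physical frame
#'   (grids may differ; distances are taken in mm).
#' @param radius_mm association radius (default 5 mm).
#' @return a `cluster_candidates` data frame with columns `seed_label`,
#'   `x_mm`, `y_mm`, `z_mm`, `n_members`, `member_voxel_count`, `score` and
#'   a list column `members` of row indices into `mcs`.
#' @export
cluster_candidates <- function(seeds, mcs, radius_mm = 5.0) {
  stopifnot(inherits(seeds, "labeled_objects"), inherits(mcs, "labeled_objects"))
  if (radius_mm <= 0) stop("`radius_mm` must be positive", call. = FALSE)
  ns <- nrow(seeds)
  mc_cent <- as.matrix(mcs[, c("x_mm", "y_mm", "z_mm"), drop = FALSE])
  mc_spacing <- attr(mcs, "spacing"); mc_origin <- attr(mcs, "origin")
  members <- vector("list", ns)
  mvc <- integer(ns); nmem <- integer(ns)
  for (s in seq_len(ns)) {
    sc <- c(seeds$x_mm[s], seeds$y_mm[s], seeds$z_mm[s])
    if (nrow(mc_cent)) {
      dd <- sqrt(colSums((t(mc_cent) - sc)^2))
      in_r <- which(dd <= radius_mm)
      in_r <- in_r[order(dd[in_r], mcs$label[in_r])]
    } else in_r <- integer()
    members[[s]] <- in_r
    nmem[s] <- length(in_r)
    cnt <- 0L
    for (m in in_r) {
      vc <- voxel_centers_mm(mcs$voxels[[m]], mc_spacing, mc_origin)
      cnt <- cnt + sum(sqrt(rowSums(sweep(vc, 2, sc)^2)) <= radius_mm)
    }
    mvc[s] <- cnt
  }
  out <- data.frame(seed_label = seeds$label,
                    x_mm = seeds$x_mm, y_mm = seeds$y_mm, z_mm = seeds$z_mm,
                    n_members = nmem, member_voxel_count = mvc,
                    score = as.numeric(mvc))
  out$members <- members
  attr(out, "seeds") <- seeds
  attr(out, "mcs") <- mcs
  attr(out, "radius_mm") <- radius_mm
  class(out) <- c("cluster_candidates", "data.frame")
  out
}

#' Write a labeled-object or cluster table as delimited text
#'
#' @param x a `labeled_objects` or `cluster_candidates` table.
#' @param path output CSV path.
#' @export
write_object_table <- function(x, path) {
  df <- as.data.frame(x)
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
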