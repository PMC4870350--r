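#' Full CADe pipeline configuration
#'
#' Bundles every stage's parameters with defaults at the reference values:
#' in-plane subsampling by 10 (0.1 mm pitch to 1 mm), objectness alpha 0.1 /
#' gamma 3.0, band-pass windows 15/7/3 pixels, ~500 seed objects, SNR3D
#' binarization at 3.2, 5 mm cluster association, and the rule-based
#' false-positive cascade.
#'
#' @param subsample_factor in-plane prescreening reduction (default 10).
#' @param objectness an [objectness_params()].
#' @param bandpass a [bandpass_spec()].
#' @param seed_target target seed-object count (default 500).
#' @param seed_tolerance relative tolerance of the seed-count search.
#' @param snr_threshold fixed SNR3D binarization level (default 3.2).
#' @param mc_fallback_target expected MC-candidate count scale (default 5000).
#' @param mc_count_targeted search for a threshold hitting
#'   `mc_fallback_target` instead of using the fixed 3.2 (default `FALSE`).
#' @param snr3d_window local neighborhood of the SNR3D statistic.
#' @param snr3d_form `"variance_over_mean"` or `"std_over_mean"`.
#' @param connectivity labeling connectivity (default 26).
#' @param cluster_radius_mm association radius (default 5 mm).
#' @param fp an [fp_params()].
#' @param fp_max FROC normalization bound in FPs/volume (default 20.44).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(subsample_factor = 10L,
                            objectness = objectness_params(),
                            bandpass = bandpass_spec(),
                            seed_target = 500L,
                            seed_tolerance = 0.1,
                            snr_threshold = 3.2,
                            mc_fallback_target = 5000L,
                            mc_count_targeted = FALSE,
                            snr3d_window = c(9L, 9L, 3L),
                            snr3d_form = "variance_over_mean",
                            connectivity = 26L,
                            cluster_radius_mm = 5.0,
                            fp = fp_params(),
                            fp_max = 20.44) {
  structure(list(subsample_factor = as.integer(subsample_factor),
                 objectness = objectness, bandpass = bandpass,
                 seed_target = as.integer(seed_target),
                 seed_tolerance = seed_tolerance,
                 snr_threshold = snr_threshold,
                 mc_fallback_target = as.integer(mc_fallback_target),
                 mc_count_targeted = isTRUE(mc_count_targeted),
                 snr3d_window = as.integer(snr3d_window),
                 snr3d_form = snr3d_form,
                 connectivity = as.integer(connectivity),
                 cluster_radius_mm = cluster_radius_mm,
                 fp = fp, fp_max = fp_max),
            class = "pipeline_config")
}

empty_labeled_objects <- function(v) {
  mask <- dbt_volume(array(0, dim = dim(v$data)), spacing = v$spacing,
                     origin = v$origin)
  connected_components(mask, 26L)
}

#' Run the full CADe pipeline on one volume
#'
#' Executes: in-plane subsampling (block max) -> multiscale Hessian
#' objectness -> slice-wise band-pass SNR enhancement -> MOR product (SNR
#' field max-pooled onto the coarse grid) -> seed-object extraction ->
#' SNR3D statistic -> MC-candidate extraction -> 5 mm cluster association
#' -> rule-based false-positive reduction -> optional scoring against
#' ground truth.  Deterministic given the volume and configuration.
#'
#' @param volume a [dbt_volume()].
#' @param truths optional `mcc_annotations` ground truth.
#' @param cfg a [pipeline_config()].
#' @param keep_intermediates return the intermediate fields and tables.
#' @return a `cade_run` list: `detections` (an `mcc_detections` table),
#'   `report` (stage counts, thresholds, timings, config echo), `match`
#'   (a `match_result`, when truths were given), and optionally
#'   `intermediates`.
#' @export
run_pipeline <- function(volume, truths = NULL, cfg = pipeline_config(),
                         keep_intermediates = FALSE) {
  stopifnot(inherits(volume, "dbt_volume"), inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sub <- stage("subsample", subsample_xy(volume, cfg$subsample_factor))
  tick("subsample")
  obj <- stage("objectness", multiscale_objectness(sub, cfg$objectness))
  tick("objectness")
  kernel <- build_bandpass_kernel(cfg$bandpass)
  snr_full <- stage("snr_enhance", snr_enhance(volume, kernel))
  snr_coarse <- subsample_xy(snr_full, cfg$subsample_factor)
  tick("snr_enhance")
  mor <- stage("mor", compute_mor(obj, snr_coarse))
  tick("mor")

  mor_flat <- max(mor$data) <= min(mor$data)
  seeds <- if (mor_flat) empty_labeled_objects(mor) else
    stage("seeds", suppressWarnings(
      extract_seed_objects(mor, cfg$seed_target, cfg$connectivity,
                           cfg$seed_tolerance)))
  tick("seeds")

  snr3d <- stage("snr3d", compute_snr3d(snr_full, cfg$snr3d_window,
                                        cfg$snr3d_form))
  mcs <- stage("mc_candidates", suppressMessages(
    extract_mc_candidates(snr3d, cfg$snr_threshold, cfg$mc_fallback_target,
                          cfg$mc_count_targeted, cfg$connectivity)))
  tick("mc_candidates")

  clusters <- stage("clustering",
                    cluster_candidates(seeds, mcs, cfg$cluster_radius_mm))
  tick("clustering")
  dets <- stage("fp_reduction",
                reduce_false_positives(clusters, seeds, mcs, cfg$fp))
  tick("fp_reduction")

  match <- NULL
  if (!is.null(truths)) {
    match <- stage("evaluation", match_detections(dets, truths))
    tick("evaluation")
  }

  report <- list(
    counts = c(seeds = nrow(seeds), mc_candidates = nrow(mcs),
               clusters = nrow(clusters), detections = nrow(dets)),
    seed_threshold = attr(seeds, "threshold"),
    mc_threshold = attr(mcs, "threshold"),
    stage_log = attr(dets, "stage_log"),
    timings_s = timings,
    config = cfg,
    version = as.character(packageVersion("tomocad")))
  out <- list(detections = dets, report = report, match = match)
  if (keep_intermediates)
    out$intermediates <- list(subsampled = sub, objectness = obj,
                              snr = snr_full, snr_coarse = snr_coarse,
                              mor = mor, snr3d = snr3d, seeds = seeds,
                              mcs = mcs, clusters = clusters)
  class(out) <- "cade_run"
  out
}

#' @export
print.cade_run <- function(x, ...) {
  cat("<cade_run>\n  stage counts:\n")
  lg <- x$report$stage_log
  for (i in seq_len(nrow(lg)))
    cat(sprintf("    %-24s %d\n", lg$stage[i], lg$n_out[i]))
  if (!is.null(x$match))
    cat(sprintf("  sensitivity %.3f, FPs %d\n",
                x$match$sensitivity, x$match$n_fp))
  invisible(x)
}

#' FROC experiment over a phantom batch
#'
#' Runs the pipeline on every volume with the false-positive rules relaxed
#' to score-only (all elimination thresholds 0, so every cluster with at
#' least one member survives as a scored cube), pools the scored detections,
#' and sweeps the score threshold into an FROC curve.  The operating point
#' of the default (unrelaxed) rule set is evaluated alongside.
#'
#' @param batch a list of `list(volume, truth)` pairs, e.g. from
#'   [phantom_batch()].
#' @param cfg a [pipeline_config()]; its `fp` slot defines the default
#'   operating point.
#' @param fp_max FROC normalization bound (defaults to `cfg$fp_max`).
#' @return a list: `froc` (an `froc_result`), `area` (normalized partial
#'   area over `[0, fp_max]`), `operating_point` (pooled metrics of the
#'   default rule set), `dets_per_volume`, `truths_per_volume`.
#' @export
run_froc_experiment <- function(batch, cfg = pipeline_config(),
                                fp_max = NULL) {
  if (length(batch) < 2)
    stop("`batch` must contain at least two volumes", call. = FALSE)
  n_truths <- vapply(batch, function(b) nrow(b$truth$clusters), integer(1))
  if (all(n_truths == 0))
    stop("`batch` must contain at least one positive volume", call. = FALSE)
  fp_max <- fp_max %||% cfg$fp_max

  relaxed <- cfg
  relaxed$fp <- fp_params(min_member_voxels = 0L, min_neighbor_seeds = 0L,
                          neighbor_radius_mm = cfg$fp$neighbor_radius_mm,
                          min_cube_mc_count = 0L, min_cube_mc_volume_mm3 = 0)

  runs <- lapply(batch, function(b)
    run_pipeline(b$volume, truths = NULL, cfg = relaxed,
                 keep_intermediates = TRUE))
  dets <- lapply(runs, `[[`, "detections")
  truths <- lapply(batch, function(b) b$truth$clusters)

  fr <- froc_curve(dets, truths)
  area <- froc_area_normalized(fr, fp_max)

  # default-threshold operating point: the enhancement stages are
  # rule-independent, so the unrelaxed cascade re-runs on the cached
  # cluster/seed/candidate tables
  strict_matches <- mapply(function(r, g) {
    it <- r$intermediates
    d <- reduce_false_positives(it$clusters, it$seeds, it$mcs, cfg$fp)
    match_detections(d, g)
  }, runs, truths, SIMPLIFY = FALSE)
  op <- case_metrics(strict_matches)

  list(froc = fr, area = area, fp_max = fp_max, operating_point = op,
       dets_per_volume = dets, truths_per_volume = truths,
       reports = lapply(runs, `[[`, "report"))
}
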