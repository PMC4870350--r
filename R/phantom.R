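#' Configuration of the synthetic DBT phantom generator
#'
#' Generates DBT-like grey-level volumes with known microcalcification
#' cluster (MCC) ground truth: bright compact Gaussian blobs grouped in
#' clusters, elongated (line) and planar distractors, a textured background,
#' and stronger blur along the slice axis emulating the interplanar
#' artifacts of limited-angle reconstruction.  Grey levels are normalized so
#' the background noise has unit standard deviation after the depth blur,
#' making contrast values and SNR-type thresholds directly comparable across
#' phantoms.
#'
#' @param dim grid size, default `c(256, 256, 40)`.
#' @param spacing voxel pitch in mm, default `c(0.1, 0.1, 1.0)` (the
#'   reference DBT geometry); a coarse 1 mm isotropic profile is available
#'   via [phantom_config_coarse()].
#' @param n_clusters number of MC clusters (default 3).
#' @param mcs_per_cluster inclusive integer range of MCs per cluster
#'   (default `c(5, 12)`).
#' @param cluster_radius_mm maximal MC offset from its cluster center
#'   (default 4 mm, inside the 5 mm association rule).
#' @param mc_diameter_mm range of MC full-width-at-half-maximum diameters
#'   in mm (default `c(0.2, 0.8)`, sub-millimetre as clinical MCs are).
#' @param mc_contrast MC peak amplitude in units of the background noise
#'   standard deviation, measured after the depth blur (default 20).
#' @param n_line_distractors,n_plane_distractors numbers of full-extent
#'   Gaussian-profile cylinders (in-plane orientation) and z-normal slabs
#'   (defaults 3 and 1).
#' @param distractor_contrast distractor peak amplitude in noise-sigma
#'   units (default 10, comparable to but below the MC contrast).
#' @param line_fwhm_mm,plane_fwhm_mm distractor cross-section widths
#'   (defaults 0.6 and 0.8 mm).
#' @param background `"correlated-noise"` (default), `"flat"`, or
#'   `"low-frequency-gradient"`.
#' @param bg_smooth_sigma_mm in-plane correlation length of the noise
#'   background (default 0.3 mm).
#' @param z_blur_sigma_mm Gaussian depth-blur scale (default 1.5 mm).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dim = c(256L, 256L, 40L),
                           spacing = c(0.1, 0.1, 1.0),
                           n_clusters = 3L,
                           mcs_per_cluster = c(5L, 12L),
                           cluster_radius_mm = 4.0,
                           mc_diameter_mm = c(0.2, 0.8),
                           mc_contrast = 20,
                           n_line_distractors = 3L,
                           n_plane_distractors = 1L,
                           distractor_contrast = 10,
                           line_fwhm_mm = 0.6,
                           plane_fwhm_mm = 0.8,
                           background = c("correlated-noise", "flat",
                                          "low-frequency-gradient"),
                           bg_smooth_sigma_mm = 0.3,
                           z_blur_sigma_mm = 1.5,
                           seed = NULL) {
  background <- match.arg(background)
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  stopifnot(length(dim) == 3, all(dim >= 8), length(spacing) == 3,
            all(spacing > 0))
  if (any(mc_diameter_mm <= 0) || diff(range(mc_diameter_mm)) < 0)
    stop("`mc_diameter_mm` must be a positive range", call. = FALSE)
  if (cluster_radius_mm <= 0) stop("`cluster_radius_mm` must be positive",
                                   call. = FALSE)
  extent <- dim * spacing
  if (any(extent[1:2] < 2 * (cluster_radius_mm + 2)) && n_clusters > 0)
    stop("grid too small to hold clusters with margin", call. = FALSE)
  structure(list(dim = dim, spacing = spacing, n_clusters = as.integer(n_clusters),
                 mcs_per_cluster = as.integer(mcs_per_cluster),
                 cluster_radius_mm = cluster_radius_mm,
                 mc_diameter_mm = as.numeric(mc_diameter_mm),
                 mc_contrast = mc_contrast,
                 n_line_distractors = as.integer(n_line_distractors),
                 n_plane_distractors = as.integer(n_plane_distractors),
                 distractor_contrast = distractor_contrast,
                 line_fwhm_mm = line_fwhm_mm, plane_fwhm_mm = plane_fwhm_mm,
                 background = background,
                 bg_smooth_sigma_mm = bg_smooth_sigma_mm,
                 z_blur_sigma_mm = z_blur_sigma_mm, seed = seed),
            class = "phantom_config")
}

#' Coarse (1 mm isotropic) phantom profile
#'
#' Matches the grid a full-resolution phantom reaches after in-plane
#' subsampling by 10; useful for fast tests of the coarse-grid stages.
#'
#' @param ... overrides passed to [phantom_config()].
#' @export
phantom_config_coarse <- function(...) {
  phantom_config(dim = c(64L, 64L, 40L), spacing = c(1, 1, 1), ...)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# attenuation of a blob's on-grid peak by the discrete z blur; used to
# pre-compensate inserted amplitudes so `contrast` is realized post-blur
z_blur_peak_factor <- function(s_z_mm, blur_sigma_mm, dz) {
  if (blur_sigma_mm <= 0) return(1)
  s_vox <- blur_sigma_mm / dz
  r <- max(1L, as.integer(ceiling(4 * s_vox)))
  w <- exp(-((-r):r)^2 / (2 * s_vox^2)); w <- w / sum(w)
  k <- (-r):r
  p <- exp(-(k * dz)^2 / (2 * s_z_mm^2))
  sum(w * p)
}

insert_blob <- function(arr, cfg, center_mm, sigma_mm, amplitude) {
  d <- dim(arr); sp <- cfg$spacing
  rng <- pmax(1, ceiling(4 * sigma_mm / sp))
  cidx <- round(center_mm / sp) + 1
  i <- max(1, cidx[1] - rng[1]):min(d[1], cidx[1] + rng[1])
  j <- max(1, cidx[2] - rng[2]):min(d[2], cidx[2] + rng[2])
  k <- max(1, cidx[3] - rng[3]):min(d[3], cidx[3] + rng[3])
  gx <- exp(-(((i - 1) * sp[1]) - center_mm[1])^2 / (2 * sigma_mm^2))
  gy <- exp(-(((j - 1) * sp[2]) - center_mm[2])^2 / (2 * sigma_mm^2))
  gz <- exp(-(((k - 1) * sp[3]) - center_mm[3])^2 / (2 * sigma_mm^2))
  arr[i, j, k] <- arr[i, j, k] + amplitude * (gx %o% gy %o% gz)
  arr
}

#' Generate a synthetic DBT phantom with ground truth
#'
#' See [phantom_config()] for the model.  Truth records (cluster boxes, MC
#' centers/diameters/contrasts, distractor geometry) describe the inserted
#' objects before the depth blur; inserted amplitudes are pre-compensated so
#' that each object's on-grid peak after the blur equals its nominal
#' contrast.
#'
#' @param cfg a [phantom_config()].
#' @return a list with elements `volume` (a [dbt_volume()]) and `truth`
#'   (list: `clusters` annotations, `mcs`, `lines`, `planes` data frames).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(cfg$seed)
  }
  d <- cfg$dim; sp <- cfg$spacing
  extent <- (d - 1) * sp # coordinates of voxel centers span [0, extent]

  ## background (pre-normalization)
  bg <- array(0, dim = d)
  if (cfg$background != "flat") {
    bg <- array(rnorm(prod(d)), dim = d)
    for (axis in 1:2) {
      s_vox <- cfg$bg_smooth_sigma_mm / sp[axis]
      if (s_vox >= 1e-8)
        bg <- conv1d_vol(bg, axis, gaussian_kernel_1d(s_vox))
    }
    if (cfg$background == "low-frequency-gradient") {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      xs <- (seq_len(d[1]) - 1) * sp[1]
      ys <- (seq_len(d[2]) - 1) * sp[2]
      zs <- (seq_len(d[3]) - 1) * sp[3]
      ramp <- outer(outer(xs * u[1], ys * u[2], `+`), zs * u[3], `+`)
      bg_sd0 <- sd(bg)
      bg <- bg + ramp / max(extent) * 5 * bg_sd0 # ~5 sigma drift end to end
    }
  }

  ## signal: clusters of MC blobs
  margin <- cfg$cluster_radius_mm + 2
  mc_rows <- list(); cl_rows <- list()
  sig <- array(0, dim = d)
  n_mc_range <- range(cfg$mcs_per_cluster)
  centers <- matrix(numeric(), ncol = 3)
  for (ci in seq_len(cfg$n_clusters)) {
    placed <- FALSE
    for (try in 1:200) {
      ctr <- c(runif(1, margin, extent[1] - margin),
               runif(1, margin, extent[2] - margin),
               runif(1, min(margin, extent[3] / 4),
                     extent[3] - min(margin, extent[3] / 4)))
      # distinct findings: keep cluster centers apart by two radii
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, ctr)^2))) >=
            2 * cfg$cluster_radius_mm) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("cluster placement failed after bounded retries",
                      call. = FALSE)
    centers <- rbind(centers, ctr)
    n_mc <- if (n_mc_range[1] == n_mc_range[2]) n_mc_range[1] else
      sample(n_mc_range[1]:n_mc_range[2], 1)
    for (mi in seq_len(n_mc)) {
      repeat { # uniform in the cluster ball
        off <- runif(3, -cfg$cluster_radius_mm, cfg$cluster_radius_mm)
        if (sum(off^2) <= cfg$cluster_radius_mm^2) break
      }
      pos <- ctr + off
      pos <- pmin(pmax(pos, 0), extent)
      # sub-slice depth positions cannot be represented at a 1 mm slice
      # interval; snap the MC depth to the nearest slice center
      pos[3] <- round(pos[3] / sp[3]) * sp[3]
      dia <- runif(1, cfg$mc_diameter_mm[1], cfg$mc_diameter_mm[2])
      s <- dia * FWHM_TO_SIGMA
      amp <- cfg$mc_contrast / z_blur_peak_factor(s, cfg$z_blur_sigma_mm, sp[3])
      sig <- insert_blob(sig, cfg, pos, s, amp)
      mc_rows[[length(mc_rows) + 1L]] <- data.frame(
        cluster = ci, x_mm = pos[1], y_mm = pos[2], z_mm = pos[3],
        diameter_mm = dia, contrast = cfg$mc_contrast)
    }
    this <- do.call(rbind, mc_rows[(length(mc_rows) - n_mc + 1):length(mc_rows)])
    pad <- c(1, 1, max(2, cfg$z_blur_sigma_mm))
    cl_rows[[ci]] <- data.frame(
      label = sprintf("cluster_%02d", ci),
      xmin_mm = min(this$x_mm) - pad[1], xmax_mm = max(this$x_mm) + pad[1],
      ymin_mm = min(this$y_mm) - pad[2], ymax_mm = max(this$y_mm) + pad[2],
      zmin_mm = min(this$z_mm) - pad[3], zmax_mm = max(this$z_mm) + pad[3])
  }

  ## line distractors: full-extent in-plane Gaussian-profile cylinders
  line_rows <- list()
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  for (li in seq_len(cfg$n_line_distractors)) {
    theta <- runif(1, 0, pi)
    p0 <- c(runif(1, 0.25, 0.75) * extent[1],
            runif(1, 0.25, 0.75) * extent[2])
    z0 <- round(runif(1, 0.2, 0.8) * extent[3] / sp[3]) * sp[3]
    s <- cfg$line_fwhm_mm * FWHM_TO_SIGMA
    amp <- cfg$distractor_contrast /
      z_blur_peak_factor(s, cfg$z_blur_sigma_mm, sp[3])
    perp <- outer(xs - p0[1], ys - p0[2],
                  function(x, y) x * sin(theta) - y * cos(theta))
    prof2d <- exp(-perp^2 / (2 * s^2))
    zfac <- exp(-(zs - z0)^2 / (2 * s^2))
    sig <- sig + amp * outer(prof2d, zfac)
    line_rows[[li]] <- data.frame(x0_mm = p0[1], y0_mm = p0[2], z0_mm = z0,
                                  theta = theta, fwhm_mm = cfg$line_fwhm_mm,
                                  contrast = cfg$distractor_contrast)
  }

  ## plane distractors: z-normal Gaussian-profile slabs
  plane_rows <- list()
  for (pi_ in seq_len(cfg$n_plane_distractors)) {
    z0 <- round(runif(1, 0.2, 0.8) * extent[3] / sp[3]) * sp[3]
    s <- cfg$plane_fwhm_mm * FWHM_TO_SIGMA
    amp <- cfg$distractor_contrast /
      z_blur_peak_factor(s, cfg$z_blur_sigma_mm, sp[3])
    zfac <- exp(-(zs - z0)^2 / (2 * s^2))
    for (k in seq_len(d[3])) if (zfac[k] > 1e-8)
      sig[, , k] <- sig[, , k] + amp * zfac[k]
    plane_rows[[pi_]] <- data.frame(z0_mm = z0, fwhm_mm = cfg$plane_fwhm_mm,
                                    contrast = cfg$distractor_contrast)
  }

  ## depth blur and normalization to unit background noise
  zblur <- function(arr) {
    s_vox <- cfg$z_blur_sigma_mm / sp[3]
    if (s_vox < 1e-8) return(arr)
    conv1d_vol(arr, 3, gaussian_kernel_1d(s_vox))
  }
  bgb <- zblur(bg)
  sdb <- sd(bgb)
  if (sdb > 0) bgb <- bgb / sdb
  vol <- dbt_volume(bgb + zblur(sig), spacing = sp, origin = c(0, 0, 0))

  empty_df <- function(...) data.frame(...)
  truth <- list(
    clusters = if (length(cl_rows)) {
      dfc <- do.call(rbind, cl_rows)
      annotations(dfc$label, dfc$xmin_mm, dfc$xmax_mm, dfc$ymin_mm,
                  dfc$ymax_mm, dfc$zmin_mm, dfc$zmax_mm,
                  provenance = "synthetic phantom")
    } else annotations(provenance = "synthetic phantom"),
    mcs = if (length(mc_rows)) do.call(rbind, mc_rows) else
      empty_df(cluster = integer(), x_mm = numeric(), y_mm = numeric(),
               z_mm = numeric(), diameter_mm = numeric(), contrast = numeric()),
    lines = if (length(line_rows)) do.call(rbind, line_rows) else
      empty_df(x0_mm = numeric(), y0_mm = numeric(), z0_mm = numeric(),
               theta = numeric(), fwhm_mm = numeric(), contrast = numeric()),
    planes = if (length(plane_rows)) do.call(rbind, plane_rows) else
      empty_df(z0_mm = numeric(), fwhm_mm = numeric(), contrast = numeric()))
  list(volume = vol, truth = truth)
}

#' Generate a mixed positive/negative phantom batch
#'
#' Emulates a reader-study dataset: a fraction of the volumes contain MC
#' clusters, the rest carry only background and distractors.  Per-volume
#' seeds are derived deterministically from `master_seed`.
#'
#' @param cfg template [phantom_config()] (its `seed` is ignored).
#' @param n_volumes number of volumes.
#' @param truth_fraction fraction of volumes containing clusters; exactly
#'   `round(truth_fraction * n_volumes)` volumes are positive.
#' @param master_seed integer master seed.
#' @return a list of `list(volume, truth)` pairs.
#' @export
phantom_batch <- function(cfg = phantom_config(), n_volumes = 20L,
                          truth_fraction = 0.5, master_seed = 1L) {
  if (truth_fraction < 0 || truth_fraction > 1)
    stop("`truth_fraction` must lie in [0, 1]", call. = FALSE)
  n_volumes <- as.integer(n_volumes)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(master_seed)
  vol_seeds <- sample.int(.Machine$integer.max - 1L, n_volumes)
  n_pos <- round(truth_fraction * n_volumes)
  positive <- seq_len(n_volumes) %in% sample.int(n_volumes, n_pos)
  lapply(seq_len(n_volumes), function(i) {
    ci <- cfg
    ci$seed <- vol_seeds[i]
    if (!positive[i]) ci$n_clusters <- 0L
    generate_phantom(ci)
  })
}
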