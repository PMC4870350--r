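#' Parameters of the multiscale Hessian objectness filter
#'
#' A bright compact blob has three large, nearly equal, negative Hessian
#' eigenvalues after Gaussian smoothing; lines and planes have at least one
#' eigenvalue near zero.  The objectness response turns that signature into a
#' voxelwise score between 0 and 1.
#'
#' Two shape-term variants are provided.  `"as_printed"` uses the ratio
#' `lam1^2 / (2 alpha^2 lam2 lam3)` with the eigenvalues sorted ascending
#' (`lam1 <= lam2 <= lam3 <= 0`); because `|lam1|` is the *largest* magnitude
#' this ratio is also maximal for line-like voxels.  The default
#' `"blobness_corrected"` uses the conventional smallest-over-largest
#' blobness ratio `lam3^2 / (2 alpha^2 |lam1 lam2|)`, which vanishes for
#' ideal lines and planes and peaks for spheres; see the methods vignette.
#'
#' @param alpha dimensionless shape sensitivity (default 0.1).
#' @param gamma structureness scale in the grey-level units of the smoothed
#'   Hessian (default 3.0).
#' @param scales Gaussian smoothing scales sigma in mm, strictly increasing.
#'   Default `c(0.5, 1, 1.5)` spans sub-voxel to ~3-voxel blobs on the
#'   1 mm subsampled grid.
#' @param mode `"blobness_corrected"` (default) or `"as_printed"`.
#' @return an `objectness_params` list.
#' @export
objectness_params <- function(alpha = 0.1, gamma = 3.0,
                              scales = c(0.5, 1.0, 1.5),
                              mode = c("blobness_corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("`alpha` must be a positive scalar", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0)
    stop("`gamma` must be a positive scalar", call. = FALSE)
  scales <- as.numeric(scales)
  if (length(scales) < 1 || any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly positive and strictly increasing",
         call. = FALSE)
  structure(list(alpha = alpha, gamma = gamma, scales = scales, mode = mode),
            class = "objectness_params")
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w / sum(w)
}

conv1d_vol <- function(arr, axis, kernel) {
  d <- dim(arr)
  out <- cpp_conv1d(as.vector(arr), as.integer(d), as.integer(axis),
                    as.numeric(kernel))
  array(out, dim = d)
}

#' Anisotropy-aware 3D Gaussian smoothing
#'
#' Separable Gaussian convolution with per-axis sigma (in voxels) equal to
#' `sigma_mm / spacing`, so a single physical scale behaves consistently on
#' anisotropic DBT grids.  Boundaries are mirror-reflected.
#'
#' @param v a [dbt_volume()].
#' @param sigma_mm positive smoothing scale in mm.
#' @return a smoothed [dbt_volume()] on the same grid.
#' @export
gaussian_smooth <- function(v, sigma_mm) {
  stopifnot(inherits(v, "dbt_volume"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1 || sigma_mm <= 0)
    stop("`sigma_mm` must be a positive scalar", call. = FALSE)
  out <- v$data
  for (axis in 1:3) {
    s_vox <- sigma_mm / v$spacing[axis]
    if (s_vox < 1e-8) next
    out <- conv1d_vol(out, axis, gaussian_kernel_1d(s_vox))
  }
  dbt_volume(out, spacing = v$spacing, origin = v$origin)
}

#' Hessian eigenvalues of the smoothed volume
#'
#' Smooths the volume at scale `sigma_mm`, takes second central differences
#' in physical units (divided by the spacing products), and diagonalizes the
#' symmetric 3x3 Hessian at every voxel.  Eigenvalues are returned in
#' ascending order, matching the bright-blob convention
#' `0 >= lam3 >= lam2 >= lam1` when all are non-positive.
#'
#' @param v a [dbt_volume()], at least 3 voxels along each axis.
#' @param sigma_mm Gaussian scale in mm.
#' @return an `n x 3` matrix of ascending eigenvalues (one row per voxel in
#'   column-major order) with attributes `dim_vol`, `spacing`, `origin`.
#' @export
hessian_eigenvalues <- function(v, sigma_mm) {
  stopifnot(inherits(v, "dbt_volume"))
  d <- dim(v$data)
  if (any(d < 3L))
    stop("volume must have at least 3 voxels along every axis", call. = FALSE)
  g <- gaussian_smooth(v, sigma_mm)$data
  h <- v$spacing
  d2 <- function(axis) conv1d_vol(g, axis, c(1, -2, 1) / h[axis]^2)
  d1 <- function(arr, axis) conv1d_vol(arr, axis, c(-1, 0, 1) / (2 * h[axis]))
  a11 <- d2(1); a22 <- d2(2); a33 <- d2(3)
  gx <- d1(g, 1)
  a12 <- d1(gx, 2); a13 <- d1(gx, 3)
  a23 <- d1(d1(g, 2), 3)
  eigs <- cpp_sym3eig(as.vector(a11), as.vector(a22), as.vector(a33),
                      as.vector(a12), as.vector(a13), as.vector(a23))
  colnames(eigs) <- c("lam1", "lam2", "lam3")
  attr(eigs, "dim_vol") <- d
  attr(eigs, "spacing") <- v$spacing
  attr(eigs, "origin") <- v$origin
  eigs
}

#' Objectness response of a Hessian eigenvalue triple
#'
#' Product of a shape term and a structureness term
#' `1 - exp(-(lam1^2 + lam2^2 + lam3^2) / (2 gamma^2))`, gated to 0 unless
#' `lam3 <= 0` (bright structures only).  See [objectness_params()] for the
#' two shape-term modes.
#'
#' @param e a length-3 numeric (one eigenvalue triple) or an `n x 3` matrix;
#'   rows are sorted ascending internally, so input order is irrelevant.
#' @param p an [objectness_params()].
#' @return non-negative response value(s) in `[0, 1)`.
#' @export
objectness_response <- function(e, p = objectness_params()) {
  if (is.null(dim(e))) e <- matrix(as.numeric(e), ncol = 3)
  if (ncol(e) != 3) stop("`e` must have three eigenvalues per row", call. = FALSE)
  if (any(!is.finite(e))) stop("eigenvalues must be finite", call. = FALSE)
  # enforce ascending order rowwise (invariance to presentation order);
  # the median is taken with min/max ops so no rounding enters
  l1 <- pmin(e[, 1], e[, 2], e[, 3])
  l3 <- pmax(e[, 1], e[, 2], e[, 3])
  l2 <- pmax(pmin(e[, 1], e[, 2]),
             pmin(pmax(e[, 1], e[, 2]), e[, 3]))
  frob2 <- l1^2 + l2^2 + l3^2
  structureness <- 1 - exp(-frob2 / (2 * p$gamma^2))
  eps <- .Machine$double.eps
  if (p$mode == "as_printed") {
    denom <- 2 * p$alpha^2 * l2 * l3
    shape <- ifelse(abs(denom) < eps * l1^2, 1, 1 - exp(-l1^2 / denom))
    shape[l1 == 0] <- 0 # all-zero triple carries no shape evidence
  } else {
    denom <- 2 * p$alpha^2 * abs(l1 * l2)
    shape <- ifelse(denom > 0, 1 - exp(-l3^2 / denom), 0)
  }
  resp <- shape * structureness
  resp[l3 > 0] <- 0 # bright-blob gate: all eigenvalues must be <= 0
  pmax(resp, 0)
}

#' Multiscale object-type response
#'
#' Evaluates the objectness response at each smoothing scale and keeps, per
#' voxel, the maximum over scales (ties broken toward the smallest scale).
#'
#' @param v a [dbt_volume()].
#' @param p an [objectness_params()].
#' @return a [dbt_volume()] of responses on the input grid.
#' @export
multiscale_objectness <- function(v, p = objectness_params()) {
  stopifnot(inherits(v, "dbt_volume"))
  best <- NULL
  for (s in p$scales) { # ascending; strict > keeps the smallest scale on ties
    e <- hessian_eigenvalues(v, s)
    resp <- objectness_response(e, p)
    if (is.null(best)) best <- resp
    else {
      upd <- resp > best
      best[upd] <- resp[upd]
    }
  }
  dbt_volume(array(best, dim = dim(v$data)), spacing = v$spacing,
             origin = v$origin)
}

#' Band-pass filter specification (three nested mean filters)
#'
#' Window sizes of the three square mean filters, in full-resolution pixels.
#' The combined kernel responds to the `M3 x M3` core relative to the annulus
#' between the `M2 x M2` and `M1 x M1` windows, with a guard ring in between;
#' the defaults 15/7/3 correspond to 1.5/0.7/0.3 mm at the 0.1 mm pitch.
#'
#' @param m1,m2,m3 odd window sizes with `m1 > m2 > m3 >= 1`.
#' @return a `bandpass_spec` list.
#' @export
bandpass_spec <- function(m1 = 15L, m2 = 7L, m3 = 3L) {
  m <- as.integer(c(m1, m2, m3))
  if (any(is.na(m)) || any(m %% 2L == 0L))
    stop("window sizes must be odd integers", call. = FALSE)
  if (!(m[1] > m[2] && m[2] > m[3] && m[3] >= 1L))
    stop("window sizes must satisfy m1 > m2 > m3 >= 1", call. = FALSE)
  structure(list(m1 = m[1], m2 = m[2], m3 = m[3]), class = "bandpass_spec")
}

#' Build the combined 2D band-pass kernel
#'
#' `F(x, y)` = mean over the `M3 x M3` core minus mean over the annulus
#' between the `M2 x M2` and `M1 x M1` windows: core weights `1 / M3^2`,
#' annulus weights `-1 / (M1^2 - M2^2)`, zero in the guard ring.  The weights
#' sum exactly to 0, so a constant background yields zero response.
#'
#' @param spec a [bandpass_spec()].
#' @return a `bandpass_kernel` with elements `weights` (`M1 x M1` matrix),
#'   `center` (index of the central pixel) and `spec`.
#' @export
build_bandpass_kernel <- function(spec = bandpass_spec()) {
  stopifnot(inherits(spec, "bandpass_spec"))
  m1 <- spec$m1; m2 <- spec$m2; m3 <- spec$m3
  off <- abs(seq_len(m1) - (m1 + 1) / 2) # distance from center, per axis
  cheb <- outer(off, off, pmax) # Chebyshev radius of each pixel
  w <- matrix(0, m1, m1)
  w[cheb <= (m3 - 1) / 2] <- 1 / m3^2
  w[cheb > (m2 - 1) / 2] <- -1 / (m1^2 - m2^2)
  structure(list(weights = w, center = c((m1 + 1) / 2, (m1 + 1) / 2),
                 spec = spec),
            class = "bandpass_kernel")
}

#' Slice-wise SNR enhancement by band-pass filtering
#'
#' Convolves every z-slice independently with the 2D band-pass kernel
#' (mirror boundary) and clamps negative responses to 0: only positive
#' local-contrast excursions carry microcalcification evidence.
#'
#' @param v a [dbt_volume()] whose slices are at least `M1` pixels in both
#'   in-plane directions.
#' @param kernel a `bandpass_kernel` from [build_bandpass_kernel()].
#' @return a [dbt_volume()] of non-negative band-pass responses.
#' @export
snr_enhance <- function(v, kernel = build_bandpass_kernel()) {
  stopifnot(inherits(v, "dbt_volume"), inherits(kernel, "bandpass_kernel"))
  d <- dim(v$data)
  m1 <- nrow(kernel$weights)
  if (d[1] < m1 || d[2] < m1)
    stop(sprintf("slices (%d x %d) are smaller than the %d x %d kernel",
                 d[1], d[2], m1, m1), call. = FALSE)
  spec <- kernel$spec
  if (!is.null(spec) && kernel_matches_spec(kernel)) {
    # separable fast path: difference of box means, x then y per box
    box <- function(arr, m) {
      k <- rep(1 / m, m)
      conv1d_vol(conv1d_vol(arr, 1, k), 2, k)
    }
    mean3 <- box(v$data, spec$m3)
    sum1 <- box(v$data, spec$m1) * spec$m1^2
    sum2 <- box(v$data, spec$m2) * spec$m2^2
    out <- mean3 - (sum1 - sum2) / (spec$m1^2 - spec$m2^2)
  } else {
    out <- conv2d_slices(v$data, kernel$weights)
  }
  out <- pmax(out, 0)
  dbt_volume(array(out, dim = d), spacing = v$spacing, origin = v$origin)
}

kernel_matches_spec <- function(kernel) {
  ref <- build_bandpass_kernel(kernel$spec)
  isTRUE(max(abs(ref$weights - kernel$weights)) < 1e-12)
}

# direct 2D correlation of every slice with an arbitrary kernel,
# mirror-reflected boundary; used for non-standard kernels
conv2d_slices <- function(arr, w) {
  d <- dim(arr)
  r <- (nrow(w) - 1) / 2
  fold <- function(idx, n) {
    p <- 2 * n
    m <- ((idx - 1) %% p + p) %% p
    ifelse(m >= n, p - 1 - m, m) + 1
  }
  fi <- fold((1 - r):(d[1] + r), d[1])
  fj <- fold((1 - r):(d[2] + r), d[2])
  padded <- arr[fi, fj, , drop = FALSE]
  out <- array(0, dim = d)
  for (u in seq_len(nrow(w))) {
    for (vv in seq_len(ncol(w))) {
      if (w[u, vv] == 0) next
      out <- out + w[u, vv] *
        padded[u:(u + d[1] - 1), vv:(vv + d[2] - 1), , drop = FALSE]
    }
  }
  out
}

#' Multiscale object-type response weighted by the SNR image
#'
#' Voxelwise product of the objectness field and the (non-negative)
#' SNR-enhanced field; both highlight microcalcifications, so the product
#' suppresses voxels supported by only one kind of evidence.  The two fields
#' must already live on the same grid (use [subsample_xy()] to pool a
#' full-resolution SNR field onto the objectness grid).
#'
#' @param objectness,snr [dbt_volume()]s on an identical grid.
#' @return a [dbt_volume()] of non-negative MOR values.
#' @export
compute_mor <- function(objectness, snr) {
  stopifnot(inherits(objectness, "dbt_volume"), inherits(snr, "dbt_volume"))
  stopifnot_same_grid(objectness, snr, "objectness and SNR fields")
  dbt_volume(objectness$data * pmax(snr$data, 0),
             spacing = objectness$spacing, origin = objectness$origin)
}
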