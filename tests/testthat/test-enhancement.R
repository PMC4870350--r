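test_that("gaussian smoothing preserves constants, mass, and widens blobs", {
  v <- dbt_volume(array(3.7, dim = c(8, 8, 5)))
  g <- gaussian_smooth(v, 0.5)
  expect_equal(g$data, v$data, tolerance = 1e-12)

  # normalized kernel: an impulse keeps its total mass
  imp <- array(0, dim = c(15, 15, 9)); imp[8, 8, 5] <- 2
  gi <- gaussian_smooth(dbt_volume(imp, spacing = c(1, 1, 1)), 1.2)
  expect_equal(sum(gi$data), 2, tolerance = 1e-9)

  # analytic blob of width s smoothed with sigma -> width sqrt(s^2+sigma^2),
  # peak scaled by (s^2/(s^2+sigma^2))^(3/2)
  sp <- c(0.25, 0.25, 0.25); d <- c(65, 65, 65)
  s <- 2; sigma <- 1
  ctr <- (d - 1) / 2 * sp
  blob <- analytic_blob(d, sp, ctr, s)
  sm <- gaussian_smooth(dbt_volume(blob, spacing = sp), sigma)
  expected_peak <- (s^2 / (s^2 + sigma^2))^(3 / 2)
  expect_equal(sm$data[33, 33, 33], expected_peak, tolerance = 1e-3)

  expect_error(gaussian_smooth(v, -1), "positive")
})

test_that("smoothing uses per-axis sigma in voxels on anisotropic grids", {
  # same physical blur on two grids differing only in stated spacing
  set.seed(3)
  arr <- array(rnorm(20 * 20 * 20), dim = c(20, 20, 20))
  iso <- gaussian_smooth(dbt_volume(arr, spacing = c(1, 1, 1)), 2)
  # on a grid claiming 0.5 mm voxels, 1 mm sigma is the same voxel sigma
  half <- gaussian_smooth(dbt_volume(arr, spacing = c(0.5, 0.5, 0.5)), 1)
  expect_equal(iso$data, half$data, tolerance = 1e-12)
})

test_that("Hessian eigenvalues of an isotropic blob match the closed form", {
  sp <- c(0.25, 0.25, 0.25); d <- c(65, 65, 65)
  s <- 2; sigma <- 1
  ctr <- (d - 1) / 2 * sp
  v <- dbt_volume(analytic_blob(d, sp, ctr, s), spacing = sp)
  e <- hessian_eigenvalues(v, sigma)
  centre <- 33 + 65 * (32 + 65 * 32)
  a2 <- s^2 + sigma^2
  expected <- -(s^2 / a2)^(3 / 2) / a2
  expect_equal(unname(e[centre, ]), rep(expected, 3), tolerance = 1e-2)
  # the three eigenvalues agree with one another much more tightly
  expect_lt(diff(range(e[centre, ])) / abs(mean(e[centre, ])), 1e-6)
})

test_that("Hessian eigenvalues: constants give zero, ridges give one null direction", {
  v <- dbt_volume(array(5, dim = c(8, 8, 8)), spacing = c(1, 1, 1))
  e <- hessian_eigenvalues(v, 1)
  expect_lt(max(abs(e)), 1e-12)

  # 2D Gaussian profile extruded along z: lam3 ~ 0, two negative
  sp <- c(0.25, 0.25, 0.25); d <- c(49, 49, 25)
  xs <- ((seq_len(d[1]) - 1) * sp[1] - 6)^2
  ys <- ((seq_len(d[2]) - 1) * sp[2] - 6)^2
  prof <- exp(-outer(xs, ys, `+`) / (2 * 1.5^2))
  ridge <- array(rep(prof, d[3]), dim = d)
  er <- hessian_eigenvalues(dbt_volume(ridge, spacing = sp), 0.5)
  centre <- 25 + d[1] * (24 + d[2] * 12)
  expect_lt(abs(er[centre, 3]), 1e-6 * abs(er[centre, 1]))
  expect_lt(er[centre, 1], 0)
  expect_lt(er[centre, 2], 0)

  expect_error(hessian_eigenvalues(
    dbt_volume(array(0, dim = c(2, 5, 5))), 1), "at least 3")
})

test_that("objectness response reproduces the printed spot value in both modes", {
  for (mode in c("blobness_corrected", "as_printed")) {
    p <- objectness_params(alpha = 0.1, gamma = 3.0, mode = mode)
    r <- objectness_response(c(-1, -1, -1), p)
    expect_equal(r, (1 - exp(-1 / 0.02)) * (1 - exp(-3 / 18)), tolerance = 1e-10)
    expect_equal(r, 0.15352, tolerance = 1e-4)
  }
})

test_that("objectness gates and discriminates shapes", {
  p <- objectness_params()
  expect_equal(objectness_response(c(-1, -1, 0), p), 0)   # ideal line
  expect_equal(objectness_response(c(-1, 0, 0), p), 0)    # ideal plane
  expect_equal(objectness_response(c(0, 0, 0), p), 0)     # no structure
  expect_equal(objectness_response(c(-1, -2, 1), p), 0)   # bright gate
  for (a in c(0.1, 1, 10))
    expect_gt(objectness_response(c(-a, -a, -a), p), 0)   # spheres respond
})

test_that("objectness is invariant to eigenvalue presentation order", {
  set.seed(5)
  p <- objectness_params()
  for (i in 1:50) {
    e <- sort(-rexp(3))
    perm <- sample(e)
    expect_identical(objectness_response(e, p), objectness_response(perm, p))
  }
})

test_that("scaling eigenvalues up never decreases the structureness term", {
  set.seed(6)
  # on equal triples the shape term is exactly 1 in both modes, so the
  # response isolates the structureness term
  for (i in 1:25) {
    a <- rexp(1); c_ <- 1 + rexp(1)
    r1 <- objectness_response(c(-a, -a, -a), objectness_params())
    r2 <- objectness_response(c(-a, -a, -a) * c_, objectness_params())
    expect_gte(r2, r1)
  }
})

test_that("multiscale objectness equals the pointwise max over single scales", {
  set.seed(8)
  v <- dbt_volume(array(rnorm(10 * 10 * 6), dim = c(10, 10, 6)),
                  spacing = c(1, 1, 1))
  p <- objectness_params(scales = c(0.6, 1.0, 1.7))
  multi <- multiscale_objectness(v, p)
  singles <- lapply(p$scales, function(s)
    multiscale_objectness(v, objectness_params(scales = s))$data)
  expect_equal(multi$data, pmax(singles[[1]], singles[[2]], singles[[3]]),
               tolerance = 1e-12)
  # degenerate single-scale list
  expect_equal(multiscale_objectness(v, objectness_params(scales = 1))$data,
               singles[[2]], tolerance = 1e-12)
})

test_that("a spherical blob's objectness peaks at the blob center", {
  sp <- c(1, 1, 1); d <- c(21, 21, 21)
  v <- dbt_volume(analytic_blob(d, sp, c(10, 10, 10), 1.5, 20), spacing = sp)
  o <- multiscale_objectness(v, objectness_params())
  peak <- arrayInd(which.max(o$data), d)
  expect_lte(max(abs(peak - c(11, 11, 11))), 1)
})

test_that("band-pass kernel has the documented weights and symmetries", {
  k <- build_bandpass_kernel(bandpass_spec(15, 7, 3))
  w <- k$weights
  expect_equal(sum(w), 0, tolerance = 1e-14)
  expect_equal(w[8, 8], 1 / 9)
  expect_equal(w[1, 1], -1 / (15^2 - 7^2))
  expect_equal(sum(w == 1 / 9), 9)           # 3x3 core
  expect_equal(sum(w == -1 / 176), 176)      # annulus count 15^2 - 7^2
  expect_equal(sum(w == 0), 7^2 - 3^2)       # guard ring

  # property: zero sum and 4-fold symmetry for random valid specs
  set.seed(9)
  for (i in 1:20) {
    m3 <- 2 * sample(0:2, 1) + 1
    m2 <- m3 + 2 * sample(1:3, 1)
    m1 <- m2 + 2 * sample(1:3, 1)
    wi <- build_bandpass_kernel(bandpass_spec(m1, m2, m3))$weights
    expect_equal(sum(wi), 0, tolerance = 1e-13)
    expect_identical(wi, t(wi))                       # reflection
    expect_identical(wi, wi[nrow(wi):1, ])            # flip
    expect_identical(wi, t(wi)[, ncol(wi):1])         # 90 degree rotation
  }
  expect_error(bandpass_spec(7, 15, 3), "m1 > m2 > m3")
  expect_error(bandpass_spec(15, 8, 3), "odd")
})

test_that("SNR enhancement suppresses constants and responds to impulses", {
  k <- build_bandpass_kernel()
  flat <- dbt_volume(array(100, dim = c(20, 20, 3)))
  expect_equal(max(abs(snr_enhance(flat, k)$data)), 0, tolerance = 1e-10)

  imp <- array(0, dim = c(31, 31, 1)); imp[16, 16, 1] <- 1
  r <- snr_enhance(dbt_volume(imp), k)
  expect_equal(r$data[16, 16, 1], 1 / 9, tolerance = 1e-12)
  expect_equal(r$data[16, 10, 1], 0) # negative annulus response clamped

  expect_error(snr_enhance(dbt_volume(array(0, dim = c(10, 10, 2))), k),
               "smaller than")
})

test_that("SNR enhancement is slice-independent and shift-equivariant", {
  set.seed(10)
  slice <- matrix(rnorm(30 * 30), 30, 30)
  v <- dbt_volume(array(c(slice, slice), dim = c(30, 30, 2)))
  r <- snr_enhance(v)
  expect_identical(r$data[, , 1], r$data[, , 2])

  big <- array(0, dim = c(50, 50, 1))
  big[18:22, 18:22, 1] <- matrix(rnorm(25), 5, 5)
  shifted <- array(0, dim = c(50, 50, 1))
  shifted[23:27, 21:25, 1] <- big[18:22, 18:22, 1]
  r1 <- snr_enhance(dbt_volume(big))$data
  r2 <- snr_enhance(dbt_volume(shifted))$data
  expect_equal(r2[16:34, 14:32, 1], r1[11:29, 11:29, 1], tolerance = 1e-10)
})

test_that("separable fast path agrees with direct 2D convolution", {
  set.seed(12)
  v <- dbt_volume(array(rnorm(40 * 40 * 3), dim = c(40, 40, 3)))
  k <- build_bandpass_kernel()
  fast <- snr_enhance(v, k)
  generic <- k; generic$spec <- NULL # force the direct per-slice path
  slow <- snr_enhance(v, generic)
  expect_equal(fast$data, slow$data, tolerance = 1e-10)
})

test_that("MOR is the voxelwise product with grid checking", {
  set.seed(13)
  o <- dbt_volume(array(runif(8 * 8 * 4), dim = c(8, 8, 4)))
  z <- dbt_volume(array(0, dim = c(8, 8, 4)))
  one <- dbt_volume(array(1, dim = c(8, 8, 4)))
  s <- dbt_volume(array(runif(8 * 8 * 4), dim = c(8, 8, 4)))
  expect_equal(max(compute_mor(o, z)$data), 0)
  expect_equal(compute_mor(o, one)$data, o$data)
  expect_true(all(compute_mor(o, s)$data <= max(o$data) * max(s$data)))
  bad <- dbt_volume(array(1, dim = c(8, 8, 4)), spacing = c(1, 1, 1))
  expect_error(compute_mor(o, bad), "share grid")
})
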