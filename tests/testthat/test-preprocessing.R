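# Resampling, Z-score normalization and the wavelet bank.

test_that("resampling is the identity at target spacing and preserves constants", {
  vol <- random_volume(c(5, 6, 7), seed = 3)
  msk <- roi_mask(array(TRUE, c(5, 6, 7)))
  out <- resample_isotropic(vol, msk, c(1, 1, 1))
  expect_identical(out$volume$intensities, vol$intensities)

  cvol <- image_volume(array(4.2, c(4, 4, 4)), spacing_mm = c(2, 1.5, 0.7))
  out2 <- resample_isotropic(cvol, roi_mask(array(TRUE, c(4, 4, 4))))
  expect_true(all(abs(out2$volume$intensities - 4.2) < 1e-12))
  expect_equal(out2$volume$spacing_mm, c(1, 1, 1))
})

test_that("trilinear resampling matches a brute-force interpolation oracle", {
  dims <- c(4, 4, 4)
  set.seed(11)
  arr <- array(rnorm(prod(dims)), dims)
  arr[, , ] <- arr + slice.index(arr, 1)          # add a ramp along x
  vol <- image_volume(arr, spacing_mm = c(2, 2, 2))
  msk <- roi_mask(array(TRUE, dims))
  out <- resample_isotropic(vol, msk, c(1, 1, 1))
  expect_true(all(abs(dim(out$volume$intensities) - 8) <= 1))

  # independent scalar trilinear oracle, clamped at the grid edge
  tri <- function(a, x, y, z) {
    cl <- function(v, n) min(max(v, 1), n)
    x <- cl(x, dim(a)[1]); y <- cl(y, dim(a)[2]); z <- cl(z, dim(a)[3])
    x0 <- min(floor(x), dim(a)[1] - 1); y0 <- min(floor(y), dim(a)[2] - 1)
    z0 <- min(floor(z), dim(a)[3] - 1)
    if (dim(a)[1] == 1) x0 <- 1
    fx <- x - x0; fy <- y - y0; fz <- z - z0
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      v <- v + a[x0 + dx, y0 + dy, z0 + dz] *
        (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
    v
  }
  dout <- dim(out$volume$intensities)
  for (probe in list(c(1, 1, 1), c(3, 5, 2), c(8, 8, 8), c(5, 2, 7))) {
    cont <- 1 + (probe - 1) * 1 / 2       # output center in input index space
    expect_equal(out$volume$intensities[probe[1], probe[2], probe[3]],
                 tri(arr, cont[1], cont[2], cont[3]), tolerance = 1e-6)
  }
})

test_that("resampling is idempotent at the target spacing", {
  vol <- random_volume(c(6, 5, 4), seed = 5, spacing = c(1.7, 1.1, 2.3))
  msk <- sphere_mask(6, 2.5)$voxels[, 1:5, 1:4]
  out <- resample_isotropic(vol, roi_mask(msk))
  out2 <- resample_isotropic(out$volume, out$mask)
  expect_identical(out$volume$intensities, out2$volume$intensities)
  expect_identical(out$mask$voxels, out2$mask$voxels)
})

test_that("z-normalization forces mean 0 / SD 1 and errors on constants", {
  vol <- random_volume(c(5, 5, 5), seed = 2)
  msk <- roi_mask(array(TRUE, c(5, 5, 5)))
  z <- znormalize(vol, msk)
  expect_lt(abs(mean(z$intensities)), 1e-9)
  expect_lt(abs(sqrt(mean((z$intensities - mean(z$intensities))^2)) - 1), 1e-9)
  expect_error(znormalize(image_volume(array(1, c(3, 3, 3)))), "degenerate")
})

test_that("z-normalization of {1,2,3} uses the population SD convention", {
  vol <- image_volume(array(c(1, 2, 3), c(3, 1, 1)))
  z <- znormalize(vol)
  expect_equal(as.vector(z$intensities), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-4)
  expect_equal(round(as.vector(z$intensities), 4), c(-1.2247, 0, 1.2247))
})

test_that("z-normalization is affine-invariant up to sign", {
  vol <- random_volume(c(4, 5, 6), seed = 9)
  z1 <- znormalize(vol)
  z2 <- znormalize(image_volume(-2.5 * vol$intensities + 7, vol$spacing_mm))
  expect_equal(z2$intensities, -z1$intensities, tolerance = 1e-12)
})

test_that("wavelet bank has the nine labeled bands and kills constants in H bands", {
  vol <- image_volume(array(3.3, c(4, 4, 4)))
  bank <- wavelet_bank(vol)
  expect_identical(names(bank),
                   c("Original", "LLL", "LLH", "LHL", "LHH", "HHL", "HLH",
                     "HLL", "HHH"))
  for (b in setdiff(names(bank), c("Original", "LLL")))
    expect_lt(max(abs(bank[[b]]$intensities)), 1e-12)
  expect_error(wavelet_bank(image_volume(array(1:4, c(1, 2, 2)))), "2 voxels")
})

test_that("Haar impulse response matches a direct separable convolution oracle", {
  dims <- c(4, 4, 4)
  arr <- array(0, dims)
  arr[2, 3, 2] <- 1
  bank <- wavelet_bank(image_volume(arr), family = "haar")

  reflect <- function(i, n) {                 # half-sample symmetric
    m <- (i - 1) %% (2 * n); if (m < 0) m <- m + 2 * n
    if (m < n) m + 1 else 2 * n - m
  }
  lo <- c(1, 1) / sqrt(2); hi <- c(1, -1) / sqrt(2)
  # per-voxel scalar definition of the separable filter response
  scalar_oracle <- function(lab, i, j, k) {
    fs <- lapply(strsplit(lab, "")[[1]], function(ch) if (ch == "L") lo else hi)
    v <- 0
    for (a in 1:2) for (b in 1:2) for (cc in 1:2)
      v <- v + fs[[1]][a] * fs[[2]][b] * fs[[3]][cc] *
        arr[reflect(i + a - 1, 4), reflect(j + b - 1, 4), reflect(k + cc - 1, 4)]
    v
  }
  for (lab in c("LLL", "LHL", "HHH", "HLL")) {
    got <- bank[[lab]]$intensities
    want <- array(0, dims)
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      want[i, j, k] <- scalar_oracle(lab, i, j, k)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("the wavelet bank is linear band-wise", {
  v1 <- random_volume(c(4, 5, 4), seed = 1)
  v2 <- random_volume(c(4, 5, 4), seed = 2)
  b1 <- wavelet_bank(v1); b2 <- wavelet_bank(v2)
  bs <- wavelet_bank(image_volume(v1$intensities + v2$intensities))
  for (lab in names(bs))
    expect_equal(bs[[lab]]$intensities,
                 b1[[lab]]$intensities + b2[[lab]]$intensities,
                 tolerance = 1e-12)
})
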