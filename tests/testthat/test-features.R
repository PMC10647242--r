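# Radiomic feature catalog: discretization, GLCM, GLRLM, LBP, first-order
# and shape features, checked against brute-force oracles on tiny phantoms.

# all 26 signed unit offsets, for pair-enumeration oracles
all_offsets <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

test_that("discretization maps 32 distinct values bijectively and flags constants", {
  vol <- image_volume(array(0:31 + 0, c(32, 1, 1)))
  msk <- roi_mask(array(TRUE, c(32, 1, 1)))
  d <- discretize(vol, msk, 32)
  expect_identical(as.vector(d$gray), 1:32)

  dc <- discretize(image_volume(array(7, c(3, 3, 1))),
                   roi_mask(array(TRUE, c(3, 3, 1))))
  expect_true(all(dc$gray == 1L))
  expect_true(attr(dc, "constant"))
})

test_that("discretization bin counts match an independent histogram oracle", {
  set.seed(4)
  dims <- c(5, 5, 5)
  vals <- runif(prod(dims))
  vol <- image_volume(array(vals, dims))
  d <- discretize(vol, roi_mask(array(TRUE, dims)), 8)
  edges <- seq(min(vals), max(vals), length.out = 9)
  # half-open [e_k, e_{k+1}) bins; the last bin closes at the top edge
  oracle <- sapply(1:8, function(k)
    if (k < 8) sum(vals >= edges[k] & vals < edges[k + 1])
    else sum(vals >= edges[8]))
  expect_identical(tabulate(d$gray[!is.na(d$gray)], 8), as.integer(oracle))
})

test_that("GLCM of a constant ROI has zero contrast and unit energy", {
  d <- discretize(image_volume(array(2, c(3, 3, 3))),
                  roi_mask(array(TRUE, c(3, 3, 3))))
  f <- glcm_features(d)
  expect_equal(unname(f["GLCM_Contrast"]), 0)
  expect_equal(unname(f["GLCM_Energy"]), 1)
})

test_that("GLCM matrices equal an exhaustive pair-count oracle and are symmetric", {
  ph <- integer_phantom(c(4, 4, 4), n_levels = 4, seed = 8)
  d <- discretize(ph$volume, ph$mask, 4)
  mats <- glcm_matrices(d)
  g <- d$gray
  dims <- dim(g)
  for (key in names(mats)) {
    dv <- as.integer(strsplit(key, ",")[[1]])
    counts <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      p2 <- c(i, j, k) + dv
      if (all(p2 >= 1 & p2 <= dims)) {
        a <- g[i, j, k]; b <- g[p2[1], p2[2], p2[3]]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1     # symmetrization
      }
    }
    expect_lt(max(abs(mats[[key]] - counts / sum(counts))), 1e-9)
    expect_lt(max(abs(mats[[key]] - t(mats[[key]]))), 1e-12)
  }
})

test_that("a 2x2x1 two-level sheet yields the hand-enumerated pair counts", {
  arr <- array(c(1, 1, 33, 33), c(2, 2, 1))  # levels [[1,2],[1,2]] after binning
  d <- discretize(image_volume(arr), roi_mask(array(TRUE, c(2, 2, 1))), 2)
  mats <- glcm_matrices(d)
  # along x (1,0,0): both pairs are same-level -> diagonal only
  expect_equal(mats[["1,0,0"]], matrix(c(0.5, 0, 0, 0.5), 2))
  # along y (0,1,0): both pairs cross levels -> off-diagonal only
  expect_equal(mats[["0,1,0"]], matrix(c(0, 0.5, 0.5, 0), 2))
})

test_that("GLRLM: a single constant run gives LRE = L^2, alternation gives SRE = 1", {
  L <- 6
  vol <- image_volume(array(5, c(L, 1, 1)))
  d <- discretize(vol, roi_mask(array(TRUE, c(L, 1, 1))))
  m <- glrlm_matrices(d)[["1,0,0"]]
  expect_equal(sum(m), 1)                         # one run
  expect_equal(m[1, L], 1)                        # of length L at level 1
  expect_equal(sum(m * matrix(seq_len(ncol(m))^2, nrow(m), ncol(m),
                              byrow = TRUE)), L^2)

  alt <- image_volume(array(rep(c(0, 40), 4), c(8, 1, 1)))
  da <- discretize(alt, roi_mask(array(TRUE, c(8, 1, 1))), 2)
  fa <- glrlm_features(da)
  expect_equal(unname(fa["Short_Run_Emphasis"]), 1)
})

test_that("GLRLM matrices equal a brute-force run-scanning oracle", {
  ph <- integer_phantom(c(4, 4, 4), n_levels = 3, seed = 12)
  d <- discretize(ph$volume, ph$mask, 3)
  mats <- glrlm_matrices(d)
  g <- d$gray
  dims <- dim(g)
  inb <- function(p) all(p >= 1 & p <= dims)
  for (key in names(mats)) {
    dv <- as.integer(strsplit(key, ",")[[1]])
    counts <- matrix(0, 3, max(dims) * 2)
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      p <- c(i, j, k)
      prev <- p - dv
      # run start: previous voxel out of grid or different level
      if (inb(prev) && g[prev[1], prev[2], prev[3]] == g[i, j, k]) next
      len <- 0; q <- p
      while (inb(q) && g[q[1], q[2], q[3]] == g[i, j, k]) {
        len <- len + 1; q <- q + dv
      }
      counts[g[i, j, k], len] <- counts[g[i, j, k], len] + 1
    }
    got <- mats[[key]]
    expect_lt(max(abs(got - counts[, seq_len(ncol(got)), drop = FALSE])), 1e-9)
  }
})

test_that("LBP of a constant image concentrates on one uniform bin with zero entropy", {
  vol <- image_volume(array(1, c(6, 6, 2)))
  msk <- roi_mask(array(TRUE, c(6, 6, 2)))
  f <- lbp_features(vol, msk)
  h <- f[1:10]
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 1)                  # a single occupied bin
  expect_equal(unname(f["LBP_Hist_Entropy"]), 0)
})

test_that("LBP histogram sums to one and codes match a per-pixel oracle", {
  set.seed(21)
  dims <- c(8, 8, 1)
  arr <- array(0, dims)
  arr[, , 1] <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)  # checkerboard
  vol <- image_volume(arr)
  msk <- roi_mask(array(TRUE, dims))
  f <- lbp_features(vol, msk)
  expect_equal(sum(f[1:10]), 1, tolerance = 1e-12)

  # per-pixel oracle: neighbors in circular order, riu2 mapping
  off <- cbind(c(1, 1, 0, -1, -1, -1, 0, 1), c(0, 1, 1, 1, 0, -1, -1, -1))
  riu2 <- function(bits) {
    tr <- sum(bits != bits[c(2:8, 1)])
    if (tr <= 2) sum(bits) else 9
  }
  bins <- integer(0)
  for (i in 2:7) for (j in 2:7) {
    bits <- sapply(1:8, function(p)
      as.integer(arr[i + off[p, 1], j + off[p, 2], 1] >= arr[i, j, 1]))
    bins <- c(bins, riu2(bits))
  }
  oracle_h <- tabulate(bins + 1L, 10) / length(bins)
  expect_equal(unname(f[1:10]), oracle_h, tolerance = 1e-12)
})

test_that("first-order statistics are exact on tiny ROIs", {
  vol <- image_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  msk <- roi_mask(array(TRUE, c(4, 1, 1)))
  f <- first_order_and_shape(vol, msk, shape = FALSE)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Median"]), 2.5)
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["Variance"]), 1.25)   # population convention
})

test_that("single-voxel ROI has unit volume and zero variance", {
  dims <- c(5, 5, 5)
  m <- array(FALSE, dims); m[3, 3, 3] <- TRUE
  vol <- random_volume(dims, seed = 2)
  f <- first_order_and_shape(vol, roi_mask(m))
  expect_equal(unname(f["Shape_Volume"]), 1)
  expect_equal(unname(f["Variance"]), 0)
})

test_that("sphericity of a digital ball approaches 1 at high resolution", {
  f <- shape_features(sphere_mask(64, 26))
  expect_lt(abs(f[["Shape_Sphericity"]] - 1), 0.02)
  expect_equal(f[["Shape_Elongation"]], 1, tolerance = 0.02)
  expect_equal(f[["Shape_Flatness"]], 1, tolerance = 0.02)
})

test_that("the full catalog emits exactly 593 uniquely named features", {
  vol <- random_volume(c(12, 12, 12), seed = 6)
  bank <- wavelet_bank(vol)
  fv <- extract_all(bank, sphere_mask(12, 4))
  expect_length(fv, 593)
  expect_identical(anyDuplicated(names(fv)), 0L)
  expect_true(all(c("LHL_Run_Length_Nonuniformity", "LHH_Long_Run_Emphasis",
                    "HLL_Variance") %in% names(fv)))
  expect_identical(names(fv), catalog_feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("extraction is deterministic and respects reduced catalogs", {
  vol <- random_volume(c(10, 10, 10), seed = 13)
  bank <- wavelet_bank(vol)
  msk <- sphere_mask(10, 3.5)
  expect_identical(extract_all(bank, msk), extract_all(bank, msk))
  red <- feature_catalog(bands = c("Original", "LLL"),
                         families = c("firstorder", "glrlm"), shape = FALSE)
  fv <- extract_all(bank, msk, red)
  expect_length(fv, 2 * (14 + 16))
})

test_that("direction-averaged GLCM/GLRLM features are invariant to 90-degree rotations", {
  ph <- integer_phantom(c(5, 5, 5), n_levels = 6, seed = 31)
  d1 <- discretize(ph$volume, ph$mask, 6)
  rot <- aperm(ph$volume$intensities, c(2, 1, 3))[5:1, , ]  # 90 deg about z
  d2 <- discretize(image_volume(rot), ph$mask, 6)
  expect_equal(glcm_features(d1), glcm_features(d2), tolerance = 1e-9)
  expect_equal(glrlm_features(d1), glrlm_features(d2), tolerance = 1e-9)
})

test_that("texture features are invariant to affine intensity rescaling", {
  ph <- integer_phantom(c(5, 5, 5), n_levels = 8, seed = 17)
  d1 <- discretize(ph$volume, ph$mask, 8)
  d2 <- discretize(image_volume(3.7 * ph$volume$intensities + 11), ph$mask, 8)
  expect_equal(glcm_features(d1), glcm_features(d2), tolerance = 1e-9)
  expect_equal(glrlm_features(d1), glrlm_features(d2), tolerance = 1e-9)
})
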