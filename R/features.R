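# Radiomic feature catalog: intensity discretization, GLCM/GLRLM texture
# matrices averaged over the 13 unique 3D directions, slice-wise LBP
# histograms, first-order statistics and mesh-based shape descriptors.
# The default catalog emits exactly 593 named features per ROI:
# (14 first-order + 22 GLCM + 16 GLRLM + 13 LBP) x 9 bands + 8 shape.

.deltarad_cache <- new.env(parent = emptyenv())

# 13 unique displacement vectors of 26-connectivity modulo sign
glcm_directions <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dx > 0 | (d$dx == 0 & d$dy > 0) | (d$dx == 0 & d$dy == 0 & d$dz > 0)
  as.matrix(d[keep, , drop = FALSE])
}

#' Discretize ROI intensities into equal-width gray levels
#'
#' Bins the intensities of ROI voxels into `n_levels` equal-width bins over
#' the observed ROI range; levels run 1..`n_levels`. A constant ROI yields a
#' single-level result flagged via `attr(x, "constant")` rather than an error.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [roi_mask()] with at least one foreground voxel.
#' @param n_levels Number of gray levels (default 32).
#' @return Object of class `discretized_roi`: a 3D integer grid (`NA`
#'   outside the ROI), `n_levels`, and the `bin_edges` used.
#' @export
discretize <- function(volume, mask, n_levels = 32L) {
  check_volume_mask(volume, mask)
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 1L)
  vals <- volume$intensities[mask$voxels]
  if (length(vals) == 0L) stop("degenerate ROI: empty mask")
  rng <- range(vals)
  gray <- array(NA_integer_, dim(volume$intensities))
  constant <- rng[1] == rng[2]
  if (constant) {
    gray[mask$voxels] <- 1L
    edges <- c(rng[1], rng[1])
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_levels + 1L)
    lev <- pmin(n_levels, floor((vals - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L)
    gray[mask$voxels] <- as.integer(lev)
  }
  structure(
    list(gray = gray, n_levels = n_levels, bin_edges = edges,
         spacing_mm = volume$spacing_mm),
    class = "discretized_roi", constant = constant
  )
}

## ---- GLCM ------------------------------------------------------------------

axis_range <- function(n, d) {
  lo <- max(1L, 1L - d); hi <- min(n, n - d)
  if (lo > hi) integer(0) else lo:hi
}

#' Per-direction gray-level co-occurrence matrices
#'
#' One symmetrized, normalized co-occurrence matrix per direction at voxel
#' distance 1, for the 13 unique 3D directions; voxel pairs must both lie
#' inside the ROI. Directions with no valid pair are dropped.
#'
#' @param d A [discretize()]d ROI.
#' @return Named list of `n_levels x n_levels` probability matrices.
#' @export
glcm_matrices <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  g <- d$gray
  ng <- d$n_levels
  dims <- dim(g)
  dirs <- glcm_directions()
  out <- list()
  for (r in seq_len(nrow(dirs))) {
    dx <- dirs[r, 1]; dy <- dirs[r, 2]; dz <- dirs[r, 3]
    ax <- axis_range(dims[1], dx); ay <- axis_range(dims[2], dy)
    az <- axis_range(dims[3], dz)
    a <- g[ax, ay, az]
    b <- g[ax + dx, ay + dy, az + dz]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    counts <- tabulate(a[ok] + (b[ok] - 1L) * ng, nbins = ng * ng)
    m <- matrix(counts, ng, ng)
    m <- m + t(m)
    out[[paste(dx, dy, dz, sep = ",")]] <- m / sum(m)
  }
  if (length(out) == 0L) stop("GLCM requires at least one in-ROI voxel pair")
  out
}

glcm_feature_names <- function() paste0("GLCM_", c(
  "Autocorrelation", "Cluster_Prominence", "Cluster_Shade", "Cluster_Tendency",
  "Contrast", "Correlation", "Difference_Average", "Difference_Entropy",
  "Difference_Variance", "Energy", "Entropy", "Homogeneity",
  "Inverse_Difference_Moment", "Inverse_Difference_Moment_Normalized",
  "Inverse_Difference_Normalized", "Information_Correlation_1",
  "Information_Correlation_2", "Joint_Average", "Maximum_Probability",
  "Sum_Average", "Sum_Entropy", "Variance"
))

log2p <- function(p) ifelse(p > 0, log2(p), 0)

glcm_features_one <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)                         # p is symmetric: px == py
  mu <- sum(seq_len(ng) * px)              # joint average
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  psum <- tapply(as.vector(p), as.vector(i + j), sum)        # k = 2..2ng
  ksum <- as.numeric(names(psum))
  pdif <- tapply(as.vector(p), as.vector(abs(i - j)), sum)   # k = 0..ng-1
  kdif <- as.numeric(names(pdif))
  hxy <- -sum(p * log2p(p))
  pxy_outer <- px[i] * px[j]
  hxy1 <- -sum(p * log2p(pxy_outer))
  hxy2 <- -sum(pxy_outer * log2p(pxy_outer))
  hx <- -sum(px * log2p(px))
  da <- sum(kdif * pdif)
  autoc <- sum(i * j * p)
  c(
    autoc,
    sum((i + j - 2 * mu)^4 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i - j)^2 * p),
    if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    da,
    -sum(pdif * log2p(pdif)),
    sum((kdif - da)^2 * pdif),
    sum(p^2),
    hxy,
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + ((i - j) / ng)^2)),
    sum(p / (1 + abs(i - j) / ng)),
    if (hx > 0) (hxy - hxy1) / hx else 0,
    sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    mu,
    max(p),
    sum(ksum * psum),
    -sum(psum * log2p(psum)),
    sum((i - mu)^2 * p)
  )
}

#' GLCM texture features averaged over the 13 3D directions
#'
#' The 22 co-occurrence features are computed per direction and then
#' averaged, the 3D rotation-invariant aggregation scheme.
#'
#' @param d A [discretize()]d ROI with at least 2 voxels.
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(d) {
  mats <- glcm_matrices(d)
  per_dir <- vapply(mats, glcm_features_one, numeric(22))
  out <- rowMeans(per_dir)
  names(out) <- glcm_feature_names()
  out
}

## ---- GLRLM -----------------------------------------------------------------

# line decomposition of a grid along direction d, cached by (dims, d):
# `ord` sorts voxels line-major then along-line, `newline` flags line starts
glrlm_line_order <- function(dims, dvec) {
  key <- paste(c(dims, dvec), collapse = "_")
  hit <- .deltarad_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  x <- idx[, 1]; y <- idx[, 2]; z <- idx[, 3]
  k1 <- dvec[2] * x - dvec[1] * y
  k2 <- dvec[3] * x - dvec[1] * z
  k3 <- dvec[3] * y - dvec[2] * z
  pos <- dvec[1] * x + dvec[2] * y + dvec[3] * z
  o <- order(k1, k2, k3, pos)
  n <- length(o)
  nl <- c(TRUE, k1[o][-1] != k1[o][-n] | k2[o][-1] != k2[o][-n] |
            k3[o][-1] != k3[o][-n])
  res <- list(ord = o, newline = nl)
  .deltarad_cache[[key]] <- res
  res
}

#' Per-direction gray-level run-length matrices
#'
#' Counts maximal runs of identical gray level along each of the 13 unique
#' 3D directions; voxels outside the ROI break runs.
#'
#' @param d A [discretize()]d ROI.
#' @return Named list of `n_levels x max_run_length` count matrices.
#' @export
glrlm_matrices <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  g <- d$gray
  g[is.na(g)] <- 0L
  dims <- dim(g)
  ng <- d$n_levels
  maxlen <- max(dims) * 2L   # safe upper bound incl. diagonals
  dirs <- glcm_directions()
  out <- list()
  for (r in seq_len(nrow(dirs))) {
    lo <- glrlm_line_order(dims, dirs[r, ])
    v <- g[lo$ord]
    n <- length(v)
    brk <- lo$newline | c(TRUE, v[-1] != v[-n])
    starts <- which(brk)
    lens <- diff(c(starts, n + 1L))
    levs <- v[starts]
    keep <- levs > 0L
    counts <- tabulate(levs[keep] + (lens[keep] - 1L) * ng, nbins = ng * maxlen)
    m <- matrix(counts, ng, maxlen)
    lmax <- max(1L, max(which(colSums(m) > 0)))
    out[[paste(dirs[r, ], collapse = ",")]] <- m[, seq_len(lmax), drop = FALSE]
  }
  out
}

glrlm_feature_names <- function() c(
  "Short_Run_Emphasis", "Long_Run_Emphasis",
  "Gray_Level_Nonuniformity", "Gray_Level_Nonuniformity_Normalized",
  "Run_Length_Nonuniformity", "Run_Length_Nonuniformity_Normalized",
  "Run_Percentage",
  "Low_Gray_Level_Run_Emphasis", "High_Gray_Level_Run_Emphasis",
  "Short_Run_Low_Gray_Level_Emphasis", "Short_Run_High_Gray_Level_Emphasis",
  "Long_Run_Low_Gray_Level_Emphasis", "Long_Run_High_Gray_Level_Emphasis",
  "Gray_Level_Variance", "Run_Length_Variance", "Run_Entropy"
)

glrlm_features_one <- function(m, np) {
  ng <- nrow(m); nl <- ncol(m)
  gl <- matrix(seq_len(ng), ng, nl)
  rl <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  nr <- sum(m)
  p <- m / nr
  rg <- rowSums(m)   # per gray level
  rr <- colSums(m)   # per run length
  mug <- sum(gl * p); mul <- sum(rl * p)
  c(
    sum(m / rl^2) / nr,
    sum(m * rl^2) / nr,
    sum(rg^2) / nr,
    sum(rg^2) / nr^2,
    sum(rr^2) / nr,
    sum(rr^2) / nr^2,
    nr / np,
    sum(m / gl^2) / nr,
    sum(m * gl^2) / nr,
    sum(m / (gl^2 * rl^2)) / nr,
    sum(m * gl^2 / rl^2) / nr,
    sum(m * rl^2 / gl^2) / nr,
    sum(m * gl^2 * rl^2) / nr,
    sum(p * (gl - mug)^2),
    sum(p * (rl - mul)^2),
    -sum(p * log2p(p))
  )
}

#' GLRLM run-length features averaged over the 13 3D directions
#'
#' @param d A [discretize()]d ROI with at least 1 voxel.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(d) {
  mats <- glrlm_matrices(d)
  np <- sum(!is.na(d$gray))
  per_dir <- vapply(mats, glrlm_features_one, numeric(16), np = np)
  out <- rowMeans(per_dir)
  names(out) <- glrlm_feature_names()
  out
}

## ---- LBP -------------------------------------------------------------------

# rotation-invariant uniform (riu2) mapping for P = 8: codes 0..255 ->
# bin 0..8 = number of set bits if the circular pattern is uniform
# (<= 2 transitions), bin 9 otherwise
lbp_riu2_table <- function() {
  hit <- .deltarad_cache[["lbp_riu2"]]
  if (!is.null(hit)) return(hit)
  tab <- integer(256)
  for (code in 0:255) {
    bits <- as.integer(intToBits(code))[1:8]
    trans <- sum(bits != bits[c(2:8, 1)])
    tab[code + 1L] <- if (trans <= 2L) sum(bits) else 9L
  }
  .deltarad_cache[["lbp_riu2"]] <- tab
  tab
}

# circular neighbor order for P=8, R=1 (counter-clockwise from +x)
lbp_offsets <- function() {
  cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
        dy = c(0, 1, 1, 1, 0, -1, -1, -1))
}

lbp_codes_slice <- function(sl, msk) {
  nx <- nrow(sl); ny <- ncol(sl)
  if (nx < 3L || ny < 3L) return(integer(0))
  cx <- 2:(nx - 1); cy <- 2:(ny - 1)
  keep <- msk[cx, cy, drop = FALSE]
  if (!any(keep)) return(integer(0))
  center <- sl[cx, cy, drop = FALSE]
  code <- matrix(0L, length(cx), length(cy))
  off <- lbp_offsets()
  for (p in 1:8) {
    nb <- sl[cx + off[p, 1], cy + off[p, 2], drop = FALSE]
    code <- code + bitwShiftL(as.integer(nb >= center), p - 1L)
  }
  code[keep]
}

lbp_feature_names <- function() c(
  paste0("LBP_Uniform_", 0:8), "LBP_Nonuniform",
  "LBP_Hist_Mean", "LBP_Hist_Variance", "LBP_Hist_Entropy"
)

#' Slice-wise rotation-invariant uniform LBP histogram features
#'
#' Computes the P = 8, R = 1 rotation-invariant uniform local binary pattern
#' for every ROI pixel of every axial (xy) slice whose 8-neighborhood lies
#' inside the slice (comparison is `neighbor >= center`), pools a 10-bin
#' pattern histogram over all slices, and summarizes it. Features: the 10
#' normalized bins plus the histogram mean, variance and entropy.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [roi_mask()].
#' @return Named numeric vector of 13 features.
#' @export
lbp_features <- function(volume, mask) {
  check_volume_mask(volume, mask)
  tab <- lbp_riu2_table()
  dims <- dim(volume$intensities)
  codes <- integer(0)
  for (z in seq_len(dims[3])) {
    msk <- mask$voxels[, , z]
    if (!any(msk)) next
    codes <- c(codes, lbp_codes_slice(volume$intensities[, , z], msk))
  }
  if (length(codes) == 0L)
    stop("degenerate ROI: no interior LBP pixels on any slice")
  bins <- tab[codes + 1L]
  h <- tabulate(bins + 1L, nbins = 10L) / length(bins)
  k <- 0:9
  mu <- sum(k * h)
  out <- c(h, mu, sum((k - mu)^2 * h), -sum(h * log2p(h)))
  names(out) <- lbp_feature_names()
  out
}

## ---- first-order and shape -------------------------------------------------

first_order_names <- function() c(
  "Mean", "Variance", "Skewness", "Kurtosis", "Median", "Minimum", "Maximum",
  "Range", "Energy", "Entropy", "Uniformity", "Percentile10", "Percentile90",
  "Interquartile_Range"
)

first_order_values <- function(vals, n_bins = 32L) {
  m <- mean(vals)
  v <- mean((vals - m)^2)
  sdv <- sqrt(v)
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    h <- c(1, numeric(n_bins - 1L))
  } else {
    lev <- pmin(n_bins, floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L)
    h <- tabulate(lev, n_bins) / length(vals)
  }
  qs <- stats::quantile(vals, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  c(
    m, v,
    if (sdv > 0) mean((vals - m)^3) / sdv^3 else 0,
    if (sdv > 0) mean((vals - m)^4) / sdv^4 else 0,
    stats::median(vals), rng[1], rng[2], diff(rng),
    sum(vals^2),
    -sum(h * log2p(h)),
    sum(h^2),
    qs[1], qs[4], qs[3] - qs[2]
  )
}

shape_feature_names <- function() paste0("Shape_", c(
  "Volume", "Surface_Area", "Surface_Volume_Ratio", "Sphericity",
  "Compactness", "Max_3D_Diameter", "Elongation", "Flatness"
))

# cube corner offsets (v0..v7) and the 6-tetrahedron decomposition
.mt_corners <- cbind(
  c(0, 1, 1, 0, 0, 1, 1, 0),
  c(0, 0, 1, 1, 0, 0, 1, 1),
  c(0, 0, 0, 0, 1, 1, 1, 1)
)
.mt_tets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
)

tri_area <- function(a, b, c_) {
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# surface area of the iso-0.5 level set of `field` via marching tetrahedra
mt_surface_area <- function(field, spacing) {
  dims <- dim(field)
  if (any(dims < 2L)) return(0)
  iso <- 0.5
  sub <- function(dx, dy, dz)
    field[(1 + dx):(dims[1] - 1 + dx), (1 + dy):(dims[2] - 1 + dy),
          (1 + dz):(dims[3] - 1 + dz), drop = FALSE]
  vmin <- vmax <- sub(0, 0, 0)
  for (r in 2:8) {
    s <- sub(.mt_corners[r, 1], .mt_corners[r, 2], .mt_corners[r, 3])
    vmin <- pmin(vmin, s); vmax <- pmax(vmax, s)
  }
  active <- which(vmin <= iso & vmax > iso)
  if (length(active) == 0L) return(0)
  base <- arrayInd(active, dims - 1L) - 1L  # 0-based cell origin
  vals <- matrix(0, length(active), 8)
  for (r in 1:8) {
    s <- sub(.mt_corners[r, 1], .mt_corners[r, 2], .mt_corners[r, 3])
    vals[, r] <- s[active]
  }
  corner_phys <- function(r)
    sweep(base, 2, .mt_corners[r, ], "+") *
      matrix(spacing, nrow(base), 3, byrow = TRUE)
  interp <- function(pa, pb, va, vb) {
    t <- (iso - va) / (vb - va)
    pa + t * (pb - pa)
  }
  total <- 0
  for (t in seq_len(nrow(.mt_tets))) {
    vid <- .mt_tets[t, ]
    tv <- vals[, vid, drop = FALSE]
    ins <- tv > iso
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    pc <- lapply(vid, corner_phys)
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (length(rows) == 0L) next
      inset <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0L)
      outset <- setdiff(1:4, inset)
      P <- lapply(pc, function(m) m[rows, , drop = FALSE])
      V <- tv[rows, , drop = FALSE]
      if (length(inset) == 1L || length(outset) == 1L) {
        a <- if (length(inset) == 1L) inset else outset
        oth <- setdiff(1:4, a)
        p1 <- interp(P[[a]], P[[oth[1]]], V[, a], V[, oth[1]])
        p2 <- interp(P[[a]], P[[oth[2]]], V[, a], V[, oth[2]])
        p3 <- interp(P[[a]], P[[oth[3]]], V[, a], V[, oth[3]])
        total <- total + sum(tri_area(p1, p2, p3))
      } else {
        a <- inset[1]; b <- inset[2]; cc <- outset[1]; dd <- outset[2]
        q1 <- interp(P[[a]], P[[cc]], V[, a], V[, cc])
        q2 <- interp(P[[a]], P[[dd]], V[, a], V[, dd])
        q3 <- interp(P[[b]], P[[dd]], V[, b], V[, dd])
        q4 <- interp(P[[b]], P[[cc]], V[, b], V[, cc])
        total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
      }
    }
  }
  total
}

#' Surface area of a binary mask (mm^2)
#'
#' Extracts the 0.5 iso-surface of the (lightly smoothed) mask indicator by
#' marching tetrahedra and sums triangle areas. Smoothing (Gaussian, sigma
#' 1.2 voxels, applied only for masks of >= 64 voxels) removes the voxel
#' staircase so that e.g. a digital sphere's area converges to the smooth
#' value; tiny masks are meshed directly.
#'
#' @param mask An [roi_mask()].
#' @param spacing_mm Voxel spacing triple.
#' @return Surface area in mm^2.
#' @export
mask_surface_area <- function(mask, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$voxels
  nvox <- sum(m)
  if (nvox == 0L) stop("degenerate ROI: empty mask")
  idx <- which(m, arr.ind = TRUE)
  pad <- 6L
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dim(m))
  # embed the bounding box in a zero-padded field so the surface closes
  box <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dpad <- dim(box) + 2L * pad
  field <- array(0, dpad)
  field[pad + seq_len(dim(box)[1]), pad + seq_len(dim(box)[2]),
        pad + seq_len(dim(box)[3])] <- as.numeric(box)
  if (nvox >= 64L) field <- gaussian_smooth3d(field, 1.2)
  a <- mt_surface_area(field, spacing_mm)
  if (a <= 0) {
    # fall back to voxel-face counting for degenerate tiny masks
    a <- voxel_face_area(m, spacing_mm)
  }
  a
}

voxel_face_area <- function(m, spacing) {
  dims <- dim(m)
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  total <- 0
  shift <- function(arr, d, ax) {
    out <- array(FALSE, dim(arr))
    n <- dim(arr)[ax]
    src <- axis_range(n, d)
    if (ax == 1) out[src + d, , ] <- arr[src, , ]
    if (ax == 2) out[, src + d, ] <- arr[, src, ]
    if (ax == 3) out[, , src + d] <- arr[, , src]
    out
  }
  for (ax in 1:3) for (d in c(-1L, 1L))
    total <- total + sum(m & !shift(m, d, ax)) * areas[ax]
  total
}

# surface voxels: in mask with at least one 6-neighbor outside the grid/mask
surface_voxels <- function(m) {
  dims <- dim(m)
  surf <- array(FALSE, dims)
  idx <- which(m)
  co <- arrayInd(idx, dims)
  on_edge <- co[, 1] %in% c(1L, dims[1]) | co[, 2] %in% c(1L, dims[2]) |
    co[, 3] %in% c(1L, dims[3])
  inner <- co[!on_edge, , drop = FALSE]
  exposed <- rep(FALSE, nrow(inner))
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(inner, 2, d, "+")
    exposed <- exposed | !m[nb]
  }
  keep <- rbind(co[on_edge, , drop = FALSE], inner[exposed, , drop = FALSE])
  keep
}

max_3d_diameter <- function(m, spacing) {
  co <- surface_voxels(m)
  phys <- sweep(co - 1, 2, spacing, "*")
  n <- nrow(phys)
  if (n <= 1200L) {
    return(max(stats::dist(phys)))
  }
  # extreme points along a fixed direction fan approximate the hull vertices
  set <- integer(0)
  dirs <- .deltarad_cache[["diam_dirs"]]
  if (is.null(dirs)) {
    th <- seq(0, pi, length.out = 12)[-12]
    ph <- seq(0, 2 * pi, length.out = 24)[-24]
    g <- expand.grid(th = th, ph = ph)
    dirs <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
    .deltarad_cache[["diam_dirs"]] <- dirs
  }
  proj <- phys %*% t(dirs)
  set <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  max(stats::dist(phys[set, , drop = FALSE]))
}

#' First-order and shape features of an ROI
#'
#' First-order statistics (14) are computed from the continuous ROI
#' intensities (population moments; histogram entropy/uniformity use 32
#' equal-width bins). Shape features (8) are computed once from the mask in
#' its physical geometry: voxel-count volume, mesh surface area, their
#' ratio, sphericity, compactness, maximum 3D diameter between surface
#' voxels, and elongation/flatness from the principal axes of the voxel
#' coordinate cloud.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned, nonempty [roi_mask()].
#' @param shape If `FALSE`, skip shape features (used when looping bands).
#' @return Named numeric vector (22 features, or 14 when `shape = FALSE`).
#' @export
first_order_and_shape <- function(volume, mask, shape = TRUE) {
  check_volume_mask(volume, mask)
  vals <- volume$intensities[mask$voxels]
  if (length(vals) == 0L) stop("degenerate ROI: empty mask")
  fo <- first_order_values(vals)
  names(fo) <- first_order_names()
  if (!shape) return(fo)
  c(fo, shape_features(mask, volume$spacing_mm))
}

#' Shape features of a binary mask
#' @inheritParams mask_surface_area
#' @return Named numeric vector of 8 shape features.
#' @export
shape_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  m <- mask$voxels
  nvox <- sum(m)
  if (nvox == 0L) stop("degenerate ROI: empty mask")
  vol <- nvox * prod(spacing_mm)
  area <- mask_surface_area(mask, spacing_mm)
  co <- which(m, arr.ind = TRUE)
  phys <- sweep(co - 1, 2, spacing_mm, "*")
  if (nvox >= 2L) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
    diam <- max_3d_diameter(m, spacing_mm)
  } else {
    elong <- 1; flat <- 1; diam <- 0
  }
  out <- c(
    vol, area, area / vol,
    pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
    vol / (sqrt(pi) * area^1.5),
    diam, elong, flat
  )
  names(out) <- shape_feature_names()
  out
}

## ---- full catalog ----------------------------------------------------------

#' Default feature catalog specification
#'
#' The frozen default emits 593 features: 14 first-order + 22 GLCM +
#' 16 GLRLM + 13 LBP per band over 9 bands, plus 8 shape features. Bands
#' and families can be restricted for faster, narrower extractions.
#'
#' @param bands Band labels to extract (default all 9).
#' @param families Feature families per band.
#' @param shape Include the 8 mask shape features.
#' @param n_levels Gray levels for GLCM/GLRLM discretization (default 32).
#' @return A `feature_catalog` list.
#' @export
feature_catalog <- function(bands = wavelet_band_labels(),
                            families = c("firstorder", "glcm", "glrlm", "lbp"),
                            shape = TRUE, n_levels = 32L) {
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(all(bands %in% wavelet_band_labels()))
  structure(list(bands = bands, families = families, shape = shape,
                 n_levels = as.integer(n_levels)),
            class = "feature_catalog")
}

#' Names of all features a catalog emits, in order
#' @param catalog A [feature_catalog()].
#' @return Character vector of feature names.
#' @export
catalog_feature_names <- function(catalog = feature_catalog()) {
  fam_names <- list(
    firstorder = first_order_names(),
    glcm = glcm_feature_names(),
    glrlm = glrlm_feature_names(),
    lbp = lbp_feature_names()
  )
  per_band <- unlist(fam_names[catalog$families], use.names = FALSE)
  nm <- as.vector(vapply(catalog$bands, function(b) paste0(b, "_", per_band),
                         character(length(per_band))))
  if (catalog$shape) nm <- c(nm, shape_feature_names())
  nm
}

#' Extract the full radiomic feature vector from a wavelet bank
#'
#' Runs every catalog family on every band of the bank within the ROI;
#' shape features are computed once from the mask in the original geometry.
#' GLCM/GLRLM operate on a per-band 32-level equal-width discretization of
#' the ROI intensities.
#'
#' @param bank A [wavelet_bank()].
#' @param mask An [roi_mask()] aligned to the bank's grids.
#' @param catalog A [feature_catalog()]; the default emits 593 features.
#' @return Named numeric vector, one entry per catalog feature.
#' @export
extract_all <- function(bank, mask, catalog = feature_catalog()) {
  stopifnot(inherits(bank, "wavelet_bank"), inherits(mask, "roi_mask"))
  out <- numeric(0)
  for (b in catalog$bands) {
    vol <- bank[[b]]
    vals <- tryCatch({
      v <- numeric(0)
      if ("firstorder" %in% catalog$families)
        v <- c(v, first_order_and_shape(vol, mask, shape = FALSE))
      if (any(c("glcm", "glrlm") %in% catalog$families)) {
        d <- discretize(vol, mask, catalog$n_levels)
        if ("glcm" %in% catalog$families) v <- c(v, glcm_features(d))
        if ("glrlm" %in% catalog$families) v <- c(v, glrlm_features(d))
      }
      if ("lbp" %in% catalog$families) v <- c(v, lbp_features(vol, mask))
      v
    }, error = function(e) stop("band ", b, ": ", conditionMessage(e),
                                call. = FALSE))
    names(vals) <- paste0(b, "_", names(vals))
    out <- c(out, vals)
  }
  if (catalog$shape)
    out <- c(out, shape_features(mask, bank$Original$spacing_mm))
  out
}
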