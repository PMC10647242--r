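# Image containers and preprocessing: isotropic resampling, Z-score
# normalization, and the undecimated 3D wavelet image bank.

#' Create a 3D image volume
#'
#' Lightweight container for a 3D intensity grid with voxel spacing and
#' physical origin, the geometric substrate of the pipeline.
#'
#' @param intensities Numeric 3D array of voxel intensities (finite).
#' @param spacing_mm Positive numeric triple: voxel spacing in mm along
#'   (x, y, z) = array dimensions (1, 2, 3).
#' @param origin_mm Numeric triple, physical position of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be a positive triple")
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "image_volume"
  )
}

#' Create a binary ROI mask aligned to an image volume
#'
#' @param voxels Logical (or 0/1) 3D array marking region-of-interest voxels.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  v <- array(as.logical(voxels), dim(voxels))
  if (anyNA(v)) stop("mask voxels must be TRUE/FALSE")
  structure(list(voxels = v), class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$voxels), collapse = "x"),
      " grid, ", sum(x$voxels), " foreground voxels\n", sep = "")
  invisible(x)
}

check_volume_mask <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$intensities), dim(mask$voxels)))
    stop("mask shape does not match volume shape")
  invisible(TRUE)
}

#' Resample a volume/mask pair to a target (isotropic) spacing
#'
#' Intensities are trilinearly interpolated at the new voxel centers;
#' the mask is nearest-neighbor interpolated so it stays binary. The
#' physical extent of the grid is preserved to within one voxel.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [roi_mask()].
#' @param target_spacing Positive triple, default `c(1, 1, 1)` mm.
#' @return List with elements `volume` and `mask` on the new grid.
#' @export
resample_isotropic <- function(volume, mask, target_spacing = c(1, 1, 1)) {
  check_volume_mask(volume, mask)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be a positive triple")
  din <- dim(volume$intensities)
  sin_ <- volume$spacing_mm
  if (isTRUE(all.equal(sin_, target_spacing)))
    return(list(volume = volume, mask = mask))
  dout <- pmax(1L, as.integer(round(din * sin_ / target_spacing)))

  # continuous input index (1-based) of each output voxel center per axis
  ax_idx <- lapply(1:3, function(a) {
    phys <- (seq_len(dout[a]) - 1) * target_spacing[a]
    1 + phys / sin_[a]
  })
  grid <- expand.grid(x = ax_idx[[1]], y = ax_idx[[2]], z = ax_idx[[3]])
  cx <- grid$x; cy <- grid$y; cz <- grid$z

  clamp <- function(v, n) pmin(pmax(v, 1), n)
  f <- function(v, n) pmin(floor(v), n - 1e-9)  # keep an upper cell at edge
  x0 <- clamp(floor(cx), din[1]); x1 <- clamp(x0 + 1, din[1])
  y0 <- clamp(floor(cy), din[2]); y1 <- clamp(y0 + 1, din[2])
  z0 <- clamp(floor(cz), din[3]); z1 <- clamp(z0 + 1, din[3])
  wx <- clamp(cx, din[1]) - x0; wy <- clamp(cy, din[2]) - y0
  wz <- clamp(cz, din[3]) - z0

  at <- function(ix, iy, iz) volume$intensities[cbind(ix, iy, iz)]
  vals <-
    at(x0, y0, z0) * (1 - wx) * (1 - wy) * (1 - wz) +
    at(x1, y0, z0) * wx       * (1 - wy) * (1 - wz) +
    at(x0, y1, z0) * (1 - wx) * wy       * (1 - wz) +
    at(x1, y1, z0) * wx       * wy       * (1 - wz) +
    at(x0, y0, z1) * (1 - wx) * (1 - wy) * wz +
    at(x1, y0, z1) * wx       * (1 - wy) * wz +
    at(x0, y1, z1) * (1 - wx) * wy       * wz +
    at(x1, y1, z1) * wx       * wy       * wz
  out_int <- array(vals, dout)

  nn <- cbind(clamp(round(cx), din[1]), clamp(round(cy), din[2]),
              clamp(round(cz), din[3]))
  out_mask <- array(mask$voxels[nn], dout)
  if (!any(out_mask))
    stop("degenerate ROI: mask empty after resampling")

  list(
    volume = image_volume(out_int, target_spacing, volume$origin_mm),
    mask = roi_mask(out_mask)
  )
}

#' Z-score normalize a volume
#'
#' Centers and scales intensities to mean 0, SD 1 using the population
#' (divide-by-n) standard deviation, over either the whole image or only
#' the ROI voxels.
#'
#' @param volume An [image_volume()].
#' @param mask An aligned [roi_mask()] (used when `scope = "roi"`).
#' @param scope `"whole_image"` (default) or `"roi"`.
#' @return The normalized [image_volume()].
#' @export
znormalize <- function(volume, mask = NULL,
                       scope = c("whole_image", "roi")) {
  scope <- match.arg(scope)
  stopifnot(inherits(volume, "image_volume"))
  if (scope == "roi") {
    check_volume_mask(volume, mask)
    vals <- volume$intensities[mask$voxels]
  } else {
    vals <- as.vector(volume$intensities)
  }
  mu <- mean(vals)
  sd_ <- pop_sd(vals)
  if (sd_ <= 0)
    stop("degenerate intensities: zero variance in normalization scope")
  image_volume((volume$intensities - mu) / sd_, volume$spacing_mm,
               volume$origin_mm)
}

wavelet_filters <- function(family = c("haar", "db2")) {
  family <- match.arg(family)
  if (family == "haar") {
    lo <- c(1, 1) / sqrt(2)
    hi <- c(1, -1) / sqrt(2)
  } else {
    s3 <- sqrt(3)
    lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
    hi <- rev(lo) * c(1, -1, 1, -1)  # quadrature mirror
  }
  list(L = lo, H = hi)
}

#' Band labels of the wavelet bank, in fixed order
#' @export
wavelet_band_labels <- function() {
  c("Original", "LLL", "LLH", "LHL", "LHH", "HHL", "HLH", "HLL", "HHH")
}

#' One-level undecimated 3D wavelet decomposition
#'
#' Applies a low-pass (L) or high-pass (H) filter along each of the three
#' axes in turn, producing the eight sub-bands LLL..HHH plus the original
#' image. The transform is stationary (no decimation) so every band keeps
#' the original grid shape and spacing, and the ROI mask applies unchanged.
#' Letter order in a label is (x, y, z): `"LLH"` is low-pass along x and y,
#' high-pass along z. Boundaries use half-sample symmetric extension.
#'
#' @param volume An [image_volume()] with at least 2 voxels per axis.
#' @param family Wavelet family, `"haar"` (default) or `"db2"`.
#' @return A named list of class `wavelet_bank` with 9 [image_volume()]
#'   entries: `Original`, `LLL`, ..., `HHH`.
#' @export
wavelet_bank <- function(volume, family = c("haar", "db2")) {
  stopifnot(inherits(volume, "image_volume"))
  family <- match.arg(family)
  if (any(dim(volume$intensities) < 2L))
    stop("wavelet bank needs at least 2 voxels per axis")
  filt <- wavelet_filters(family)
  labels <- setdiff(wavelet_band_labels(), "Original")
  bands <- vector("list", length(labels) + 1L)
  names(bands) <- wavelet_band_labels()
  bands[["Original"]] <- volume
  for (lab in labels) {
    letters3 <- strsplit(lab, "")[[1]]
    arr <- volume$intensities
    for (ax in 1:3) arr <- filter_axis(arr, filt[[letters3[ax]]], ax)
    bands[[lab]] <- image_volume(arr, volume$spacing_mm, volume$origin_mm)
  }
  structure(bands, class = "wavelet_bank", family = family)
}
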