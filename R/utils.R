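# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so package functions are reproducible
#' without disturbing the caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed for a named pipeline stage
#'
#' One user-facing seed fans out to per-stage seeds by a fixed documented
#' offset table, so each stage is independently reproducible.
#' @noRd
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, retest = 211L, split = 307L, impute = 401L,
    select = 503L, cv = 601L, bootstrap = 701L, benchmark = 809L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage '", stage, "'")
  (as.integer(seed) %% 1000000L) * 1000L + off
}

#' Symmetric (half-sample) boundary index
#'
#' Maps out-of-range indices back inside `1..n` by mirror reflection
#' (`0 -> 1`, `-1 -> 2`, `n+1 -> n`, ...), the extension used by the wavelet
#' bank and Gaussian smoothing.
#' @noRd
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0L, m + period, m)
  as.integer(ifelse(m < n, m + 1L, period - m))
}

#' Apply a 1-D filter along one axis of a 3D array
#'
#' `out[i] = sum_k f[k] * x[i + k - 1]` with symmetric boundary extension;
#' output keeps the input shape (undecimated).
#' @noRd
filter_axis <- function(arr, filt, axis) {
  dims <- dim(arr)
  n <- dims[axis]
  out <- array(0, dims)
  base <- seq_len(n)
  for (k in seq_along(filt)) {
    idx <- reflect_index(base + (k - 1L), n)
    shifted <- switch(axis,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE]
    )
    out <- out + filt[k] * shifted
  }
  out
}

#' Separable Gaussian smoothing of a 3D array (sigma in voxels)
#' @noRd
gaussian_smooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  # center the kernel: filter_axis anchors taps at offset 0..L-1
  out <- arr
  for (ax in 1:3) {
    dims <- dim(out)
    n <- dims[ax]
    acc <- array(0, dims)
    base <- seq_len(n)
    for (k in seq_along(g)) {
      idx <- reflect_index(base + x[k], n)
      shifted <- switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE]
      )
      acc <- acc + g[k] * shifted
    }
    out <- acc
  }
  out
}

#' Population standard deviation (divide by n, not n-1)
#' @noRd
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
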