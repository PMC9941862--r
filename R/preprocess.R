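#' Depth- and ROI-restricted Gaussian smoothing
#'
#' Smooths every volume of a 4D series with a 3D Gaussian kernel while
#' restricting the support to voxels sharing the same (cortical depth bin,
#' ROI) cell, so no signal leaks across depth bins or visual areas. Kernel
#' weights are renormalized within each cell (masked convolution: smoothed =
#' G*(x*M) / G*M on the cell mask M), which preserves constants and leaves a
#' single-voxel cell untouched. Out-of-cell voxels pass through unchanged.
#'
#' @param series A `functional_series`.
#' @param labels A [make_slab()] label volume on the same grid.
#' @param fwhm_mm Kernel full-width-at-half-maximum, mm (0 = identity).
#' @param truncate Kernel support half-width in standard deviations.
#' @return The smoothed `functional_series`.
#' @export
masked_gaussian_smooth <- function(series, labels, fwhm_mm = 2.35,
                                   truncate = 3) {
  stopifnot(inherits(series, "functional_series"),
            inherits(labels, "label_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(series)
  shape <- dim(series$data)[1:3]
  if (!all(shape == dim(labels$depth)))
    stop("series and labels are on different grids")

  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_mm
  kern <- lapply(1:3, function(ax) gauss_band(shape[ax], sigma_vox[ax], truncate))

  bin <- bin_layers(labels$depth)
  cell <- ifelse(is.na(bin) | labels$roi == 0L, NA_integer_,
                 (labels$roi - 1L) * 3L + bin)
  dim(cell) <- shape
  nt <- dim(series$data)[4]
  halo <- ceiling(truncate * sigma_vox)
  for (cl in sort(unique(cell[!is.na(cell)]))) {
    sel <- !is.na(cell) & cell == cl
    if (sum(sel) == 0L) {
      warning("empty smoothing cell ", cl, ": voxels passed through")
      next
    }
    # crop to the cell's bounding box plus the kernel support
    w <- which(sel, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - halo, 1L)
    hi <- pmin(apply(w, 2, max) + halo, shape)
    bx <- lapply(1:3, function(a) lo[a]:hi[a])
    bshape <- hi - lo + 1L
    bkern <- lapply(1:3, function(a) gauss_band(bshape[a], sigma_vox[a],
                                                truncate))
    bsel <- sel[bx[[1]], bx[[2]], bx[[3]], drop = FALSE]
    den <- conv3_sep(array(bsel + 0, c(bshape, 1L)), bkern)
    sub <- series$data[bx[[1]], bx[[2]], bx[[3]], , drop = FALSE]
    num <- conv3_sep(array(as.vector(sub) * as.vector(bsel), c(bshape, nt)),
                     bkern)
    bm <- matrix(num, nrow = prod(bshape))
    sm <- matrix(sub, nrow = prod(bshape))
    sm[bsel, ] <- bm[bsel, ] / as.vector(den)[bsel]
    series$data[bx[[1]], bx[[2]], bx[[3]], ] <- array(sm, c(bshape, nt))
  }
  series
}

## Banded (truncated) 1D Gaussian convolution matrix, unnormalized; the
## masked-convolution quotient supplies the normalization.
gauss_band <- function(n, sigma, truncate = 3) {
  if (sigma <= 0) return(diag(n))
  h <- max(1L, ceiling(truncate * sigma))
  i <- matrix(seq_len(n), n, n)
  d <- i - t(i)
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > h] <- 0
  k
}

## Separable 3D convolution of a 4D array (x, y, z, t) via axis-wise matrix
## products with banded kernels.
conv3_sep <- function(arr, kern) {
  d <- dim(arr)
  # axis 1
  m <- matrix(arr, nrow = d[1])
  arr <- array(kern[[1]] %*% m, d)
  # axis 2
  a <- aperm(arr, c(2, 1, 3, 4))
  m <- matrix(a, nrow = d[2])
  a <- array(kern[[2]] %*% m, dim(a))
  arr <- aperm(a, c(2, 1, 3, 4))
  # axis 3
  a <- aperm(arr, c(3, 1, 2, 4))
  m <- matrix(a, nrow = d[3])
  a <- array(kern[[3]] %*% m, dim(a))
  aperm(a, c(2, 3, 1, 4))
}

#' Discrete-cosine high-pass filter
#'
#' Regresses the mean and the `K = floor(2 * duration * cutoff_hz)`
#' lowest-frequency discrete-cosine basis vectors out of every voxel time
#' series and returns residual plus mean, so subsequent percent-signal-change
#' rescaling stays well defined. The operation is a projection and hence
#' idempotent.
#'
#' @param x A `functional_series`, or a time-by-voxel numeric matrix.
#' @param cutoff_hz High-pass cutoff frequency, Hz (> 0).
#' @param tr Repetition time, s (taken from the series when `x` is one).
#' @return Filtered object of the same type as `x`.
#' @export
dct_highpass <- function(x, cutoff_hz = 0.003, tr = NULL) {
  stopifnot(cutoff_hz > 0)
  if (inherits(x, "functional_series")) {
    d <- dim(x$data)
    q <- dct_basis(d[4], x$tr, cutoff_hz)
    if (!is.null(q)) { # voxels x time layout: project without transposing
      m <- matrix(x$data, nrow = prod(d[1:3]), ncol = d[4])
      mu <- rowMeans(m)
      m <- m - mu
      m <- m - (m %*% q) %*% t(q)
      x$data <- array(m + mu, d)
    }
    return(x)
  }
  if (is.null(tr)) stop("tr is required for a plain matrix")
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  q <- dct_basis(n, tr, cutoff_hz)
  if (!is.null(q)) xc <- xc - q %*% crossprod(q, xc)
  sweep(xc, 2, mu, "+")
}

## Orthonormal basis of the K lowest-frequency discrete-cosine vectors,
## K = floor(2 * duration * cutoff); NULL when K = 0.
dct_basis <- function(n, tr, cutoff_hz) {
  k <- floor(2 * n * tr * cutoff_hz)
  if (k >= n) stop("cutoff too high: would remove the whole series")
  if (k < 1) return(NULL)
  tt <- seq_len(n)
  basis <- vapply(seq_len(k),
                  function(j) cos(pi * (2 * tt - 1) * j / (2 * n)),
                  numeric(n))
  qr.Q(qr(basis))
}

#' Percent-signal-change rescaling
#'
#' `100 * (s(t) - mean) / mean` per voxel, using the whole-series temporal
#' mean; the condition baseline is carried by the GLM intercept. Voxels with
#' a non-positive temporal mean are set to NA and counted in the
#' `invalid_voxels` attribute.
#'
#' @param series A `functional_series`.
#' @return The rescaled series (values in %).
#' @export
percent_signal_change <- function(series) {
  stopifnot(inherits(series, "functional_series"))
  d <- dim(series$data)
  m <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  mu <- rowMeans(m)
  bad <- !(mu > 0)
  m <- 100 * (m - mu) / mu
  m[bad, ] <- NA_real_
  series$data <- array(m, d)
  attr(series, "invalid_voxels") <- sum(bad)
  series
}

## Local-extremum detection with a minimum-separation constraint: candidate
## peaks are strict local maxima; among candidates closer than min_sep the
## larger one wins.
detect_peaks <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Respiration volume per time (RVT)
#'
#' Per-breath (peak minus trough amplitude) / (breath period), from
#' respiratory-belt peaks and troughs detected with a minimum-separation
#' constraint of half the expected breathing period, linearly interpolated
#' to the volume acquisition times.
#'
#' @param resp Numeric respiration trace (or data.frame with a `value`
#'   column).
#' @param fs Sampling frequency of the trace, Hz.
#' @param vol_times Volume acquisition times, s.
#' @param expected_period_s Expected breathing period, s (sets the peak
#'   separation constraint).
#' @return Numeric RVT regressor, one value per volume.
#' @export
rvt <- function(resp, fs, vol_times, expected_period_s = 60 / 16) {
  if (is.data.frame(resp)) resp <- resp$value
  min_sep <- max(1L, round(fs * expected_period_s / 2))
  pk <- detect_peaks(resp, min_sep)
  tr_ <- detect_peaks(-resp, min_sep)
  if (length(pk) < 2 || length(tr_) < 1)
    stop("no detectable breaths in respiration trace")
  t <- (seq_along(resp) - 1) / fs
  # envelope values at peak times; breath period from consecutive peaks
  trough_env <- stats::approx(t[tr_], resp[tr_], xout = t[pk], rule = 2)$y
  period <- diff(t[pk])
  period <- c(period, period[length(period)])
  val <- (resp[pk] - trough_env) / period
  stats::approx(t[pk], val, xout = vol_times, rule = 2)$y
}

#' Heart rate regressor (beats per minute)
#'
#' 60 / inter-beat interval from pulse-unit peaks, assigned to beat midpoints
#' and linearly interpolated to the volume acquisition times.
#'
#' @param pulse Numeric pulse trace (or data.frame with a `value` column).
#' @param fs Sampling frequency, Hz.
#' @param vol_times Volume acquisition times, s.
#' @param expected_period_s Expected cardiac period, s.
#' @return Numeric BPM regressor, one value per volume.
#' @export
bpm <- function(pulse, fs, vol_times, expected_period_s = 60 / 66) {
  if (is.data.frame(pulse)) pulse <- pulse$value
  min_sep <- max(1L, round(fs * expected_period_s / 2))
  pk <- detect_peaks(pulse, min_sep)
  if (length(pk) < 3) stop("no detectable beats in pulse trace")
  t <- (seq_along(pulse) - 1) / fs
  ibi <- diff(t[pk])
  mid <- t[pk][-length(pk)] + ibi / 2
  stats::approx(mid, 60 / ibi, xout = vol_times, rule = 2)$y
}
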