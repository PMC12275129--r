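#' Discard initial volumes of a BOLD series
#'
#' Scanner signal has not reached steady state during the first frames of an
#' EPI acquisition; the convention adopted here discards the first 10 of the
#' 210 dynamics, leaving 200 analysis frames.
#'
#' @param vol 4D array (x, y, z, t).
#' @param n Number of leading frames to drop (default 10).
#' @return 4D array with `nt - n` frames; attributes preserved.
#' @export
drop_initial_volumes <- function(vol, n = 10) {
  d <- check_vol4d(vol)
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer", call. = FALSE)
  if (d[4] <= n) stop("cannot drop ", n, " frames from a series of length ", d[4],
                      call. = FALSE)
  out <- vol[, , , (n + 1):d[4], drop = FALSE]
  attributes(out)$spacing <- attr(vol, "spacing")
  attributes(out)$tr <- attr(vol, "tr")
  out
}

# 1D Gaussian kernel, truncated at 4 sigma, unit mass.
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve along one axis of a 3D array with reflect padding, so a constant
# field is exactly preserved at boundaries.
conv_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  r <- (length(k) - 1L) / 2L
  d <- dim(arr)
  n <- d[axis]
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Spatial Gaussian smoothing of a 4D BOLD series
#'
#' Isotropic smoothing specified by full-width at half-maximum in mm
#' (default 6 mm), applied frame by frame as a separable convolution with
#' sigma per axis of `fwhm / (2 * sqrt(2 * log(2))) / spacing` voxels.
#' Reflect padding at the boundary keeps constant images unchanged.
#'
#' @param vol 4D array with a `spacing` attribute (mm) or explicit `spacing`.
#' @param fwhm_mm Kernel FWHM in mm; 0 is the identity.
#' @param spacing Voxel spacing in mm (length 3); default from attributes.
#' @return Smoothed 4D array.
#' @export
gaussian_smooth <- function(vol, fwhm_mm = 6, spacing = NULL) {
  d <- check_vol4d(vol)
  if (fwhm_mm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (is.null(spacing)) spacing <- vol_spacing(vol)
  if (fwhm_mm == 0) return(vol)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  ks <- lapply(sigmas, gauss_kernel_1d)
  out <- vol
  for (t in seq_len(d[4])) {
    fr <- out[, , , t]
    for (ax in 1:3) fr <- conv_axis(fr, ks[[ax]], ax)
    out[, , , t] <- fr
  }
  attributes(out)$spacing <- attr(vol, "spacing")
  attributes(out)$tr <- attr(vol, "tr")
  out
}

#' Remove a per-voxel linear trend, keeping the temporal mean
#'
#' Least-squares line removed voxel-wise; the temporal mean is restored so
#' later whole-brain mean computations stay well defined.
#'
#' @param vol 4D array with nt >= 3.
#' @return Detrended 4D array.
#' @export
linear_detrend <- function(vol) {
  d <- check_vol4d(vol)
  if (d[4] < 3) stop("need at least 3 time points to detrend", call. = FALSE)
  Y <- vol_to_mat(vol)                       # nt x nvox
  t0 <- seq_len(d[4]) - (d[4] + 1) / 2       # centered time
  slope <- crossprod(t0, Y) / sum(t0^2)      # 1 x nvox
  Y <- Y - outer(t0, drop(slope))
  out <- mat_to_vol(Y, d)
  attributes(out)$spacing <- attr(vol, "spacing")
  attributes(out)$tr <- attr(vol, "tr")
  out
}

#' Expand 6 rigid-body motion parameters to the Friston-24 nuisance set
#'
#' Columns are the 6 parameters, their one-frame lagged copies (first row
#' zero-filled), and the squares of both.
#'
#' @param mp nt x 6 numeric matrix or data frame (tx, ty, tz in mm;
#'   rx, ry, rz in radians).
#' @return nt x 24 numeric matrix.
#' @export
friston24_expand <- function(mp) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns", call. = FALSE)
  if (!all(is.finite(mp))) stop("motion parameters must be finite", call. = FALSE)
  lag <- rbind(0, mp[-nrow(mp), , drop = FALSE])
  out <- cbind(mp, lag, mp^2, lag^2)
  colnames(out) <- c(paste0("R", 1:6), paste0("R", 1:6, "_lag"),
                     paste0("R", 1:6, "_sq"), paste0("R", 1:6, "_lagsq"))
  out
}

#' Regress nuisance signals out of every voxel time series
#'
#' Ordinary least squares per voxel with an intercept always included;
#' rank-deficient regressor columns (after demeaning) are dropped with a
#' warning. The voxel temporal mean is restored after regression.
#'
#' @param vol 4D array.
#' @param regressors nt x p numeric matrix (e.g. Friston-24 plus tissue
#'   signals).
#' @param mask Optional 3D binary mask; voxels outside are left untouched.
#' @return Residual 4D array (means restored).
#' @export
nuisance_regress <- function(vol, regressors, mask = NULL) {
  d <- check_vol4d(vol)
  X <- as.matrix(regressors)
  if (nrow(X) != d[4]) stop("regressor rows must equal number of frames", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2, function(col) sum(col^2) > 1e-12)
  if (!any(keep)) {
    warning("all regressors constant after demeaning; returning input unchanged")
    return(vol)
  }
  Xc <- Xc[, keep, drop = FALSE]
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    warning("dropping ", ncol(Xc) - qrX$rank, " linearly dependent regressor column(s)")
    Xc <- Xc[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xc)
  }
  Y <- vol_to_mat(vol)
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  res <- Yc - Xc %*% qr.coef(qrX, Yc)
  res <- sweep(res, 2, mu, `+`)
  out <- mat_to_vol(res, d)
  if (!is.null(mask)) {
    stop_if_not_mask(mask, d)
    outside <- which(mask == 0)
    if (length(outside)) {
      nvox <- prod(d[1:3])
      om <- matrix(out, nrow = nvox)
      vm <- matrix(vol, nrow = nvox)
      om[outside, ] <- vm[outside, ]
      out <- array(om, dim = d)
    }
  }
  attributes(out)$spacing <- attr(vol, "spacing")
  attributes(out)$tr <- attr(vol, "tr")
  out
}

# Frequencies of the nt FFT bins at sampling interval tr.
fft_freqs <- function(nt, tr) {
  k <- 0:(nt - 1)
  f <- k / (nt * tr)
  nyq <- 1 / (2 * tr)
  # fold the second half onto negative-frequency magnitudes
  f[f > nyq + 1e-12] <- f[f > nyq + 1e-12] - 1 / tr
  abs(f)
}

#' Ideal Fourier bandpass of a BOLD series
#'
#' Boxcar filter in the discrete Fourier domain: bins with
#' `f_lo < f <= f_hi` are retained, all others (including DC, since
#' `f_lo >= 0`) are zeroed; the output is real. The two passbands of the
#' pipeline are 0–0.1164 Hz (CVR branch) and 0.01–0.08 Hz (standard branch).
#'
#' @param vol 4D array with a `tr` attribute, or pass `tr` explicitly.
#' @param f_lo,f_hi Band edges in Hz; must satisfy
#'   `0 <= f_lo < f_hi <= 1/(2 TR)`.
#' @param tr Repetition time in seconds.
#' @return Filtered 4D array (zero temporal mean).
#' @export
bandpass <- function(vol, f_lo, f_hi, tr = NULL) {
  d <- check_vol4d(vol)
  if (is.null(tr)) tr <- vol_tr(vol)
  nyq <- 1 / (2 * tr)
  if (f_lo < 0 || f_hi <= f_lo) stop("invalid band: need 0 <= f_lo < f_hi", call. = FALSE)
  if (f_hi > nyq + 1e-12) stop("band edge ", f_hi, " Hz exceeds Nyquist ", nyq, " Hz",
                               call. = FALSE)
  Y <- vol_to_mat(vol)
  f <- fft_freqs(d[4], tr)
  keep <- f > f_lo + 1e-12 & f <= f_hi + 1e-12
  keep[1] <- FALSE                            # DC always excluded
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Yf <- Re(stats::mvfft(F, inverse = TRUE)) / d[4]
  out <- mat_to_vol(Yf, d)
  attributes(out)$spacing <- attr(vol, "spacing")
  attributes(out)$tr <- attr(vol, "tr")
  out
}

#' Run the full BOLD preprocessing chain for one branch
#'
#' Two fixed orders are enforced. The CVR branch is
#' drop -> smooth -> detrend -> bandpass(0–0.1164 Hz); the standard branch
#' (feeding ALFF and FCD) is drop -> smooth -> detrend -> nuisance
#' regression -> bandpass(0.01–0.08 Hz). ALFF needs the spectrum before the
#' final bandpass, so the standard branch also returns the pre-bandpass
#' series.
#'
#' @param vol Raw 4D BOLD array.
#' @param mask 3D brain mask.
#' @param branch `"cvr"` or `"standard"`.
#' @param motion nt-matched (pre-drop) motion parameter matrix, required for
#'   the standard branch; the first `n_drop` rows are discarded with the
#'   frames.
#' @param tissue Optional extra nuisance columns (e.g. white-matter and
#'   ventricular mean signals), nt-matched pre-drop.
#' @param n_drop Leading frames to discard (default 10).
#' @param fwhm_mm Smoothing kernel FWHM (default 6 mm).
#' @param band Band in Hz; defaults to `c(0, 0.1164)` for the CVR branch and
#'   `c(0.01, 0.08)` for the standard branch.
#' @param tr Repetition time (s); default from the volume attribute.
#' @return List with `filtered` (post-bandpass series), `prefilter`
#'   (pre-bandpass series, for ALFF), `branch`, and `band`.
#' @export
preprocess_bold <- function(vol, mask, branch = c("cvr", "standard"),
                            motion = NULL, tissue = NULL, n_drop = 10,
                            fwhm_mm = 6, band = NULL, tr = NULL) {
  branch <- match.arg(branch)
  if (is.null(tr)) tr <- vol_tr(vol)
  if (is.null(band)) band <- if (branch == "cvr") c(0, 0.1164) else c(0.01, 0.08)
  stop_if_not_mask(mask, dim(vol))
  v <- drop_initial_volumes(vol, n_drop)
  v <- gaussian_smooth(v, fwhm_mm)
  v <- linear_detrend(v)
  if (branch == "standard") {
    if (is.null(motion)) stop("standard branch requires motion parameters", call. = FALSE)
    mp <- as.matrix(motion)
    if (nrow(mp) == dim(vol)[4]) mp <- mp[-seq_len(n_drop), , drop = FALSE]
    if (nrow(mp) != dim(v)[4])
      stop("motion parameter rows must match frame count", call. = FALSE)
    X <- friston24_expand(mp)
    if (!is.null(tissue)) {
      ts <- as.matrix(tissue)
      if (nrow(ts) == dim(vol)[4]) ts <- ts[-seq_len(n_drop), , drop = FALSE]
      X <- cbind(X, ts)
    }
    v <- nuisance_regress(v, X, mask)
  }
  filtered <- bandpass(v, band[1], band[2], tr = tr)
  list(filtered = filtered, prefilter = v, branch = branch, band = band)
}
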