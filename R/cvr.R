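#' Whole-brain mean time series
#'
#' Per-frame mean over mask voxels of a (band-limited) BOLD series; this is
#' the regressor of the resting-state CVR model, in which spontaneous
#' global fluctuations of arterial CO2 act as the vasoactive stimulus.
#'
#' @param vol 4D array, already filtered to the CVR band.
#' @param mask 3D binary brain mask.
#' @return Numeric vector of length nt.
#' @export
global_signal <- function(vol, mask) {
  d <- check_vol4d(vol)
  stop_if_not_mask(mask, d)
  idx <- which(mask != 0)
  Y <- matrix(vol, nrow = prod(d[1:3]))
  colMeans(Y[idx, , drop = FALSE])
}

#' Voxel-wise CVR index map
#'
#' Fits, per voxel, the general linear model
#' `y_v(t) = b0 + b1 * g(t) + e` with the whole-brain signal `g` as the
#' independent variable; the slope `b1` is the (unitless) CVR index, the
#' coupling of local BOLD fluctuation to the global low-frequency drive.
#' `g` is demeaned internally so the intercept absorbs the voxel mean.
#'
#' @param vol 4D array filtered to the CVR band.
#' @param g Global signal time series (length nt).
#' @param mask 3D binary mask; voxels outside are set to 0.
#' @return 3D array of regression slopes, with a `metric` attribute.
#' @export
cvr_index_map <- function(vol, g, mask) {
  d <- check_vol4d(vol)
  stop_if_not_mask(mask, d)
  if (length(g) != d[4]) stop("global signal length must equal nt", call. = FALSE)
  if (d[4] < 3) stop("need at least 3 frames", call. = FALSE)
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss < 1e-12)
    stop("global signal has zero variance: degenerate input or over-filtering",
         call. = FALSE)
  Y <- matrix(vol, nrow = prod(d[1:3]))       # voxels x time
  beta <- drop(Y %*% gc) / ss                 # slope per voxel (demeaned g kills b0)
  beta[mask == 0] <- 0
  out <- array(beta, dim = d[1:3])
  attr(out, "spacing") <- attr(vol, "spacing")
  attr(out, "metric") <- "cvr_index"
  out
}

#' Normalize a metric map by its whole-brain mean
#'
#' Divides every voxel by the mean over the mask so group statistics compare
#' relative, not absolute, levels; the normalized map has mask-mean 1.
#' Voxels outside the mask are zeroed and excluded from the mean. Used for
#' the relative CVR, ALFF, FCD and CBF maps alike.
#'
#' @param m 3D metric map.
#' @param mask 3D binary mask.
#' @return Normalized 3D map with attribute `normalized = TRUE`.
#' @export
relative_map <- function(m, mask) {
  if (!is.array(m) || length(dim(m)) != 3L) stop("m must be a 3D array", call. = FALSE)
  stop_if_not_mask(mask, dim(m))
  inside <- mask != 0
  mu <- mean(m[inside])
  if (abs(mu) < 1e-300) stop("mask mean is zero; cannot normalize", call. = FALSE)
  out <- m / mu
  out[!inside] <- 0
  attr(out, "spacing") <- attr(m, "spacing")
  attr(out, "metric") <- attr(m, "metric")
  attr(out, "normalized") <- TRUE
  out
}

#' Compute the relative CVR map from a CVR-branch preprocessed series
#'
#' Convenience wrapper: global signal, voxel-wise GLM slope, whole-brain
#' normalization.
#'
#' @inheritParams cvr_index_map
#' @return List with `index` (raw slope map) and `relative` (normalized map).
#' @export
cvr_map <- function(vol, mask) {
  g <- global_signal(vol, mask)
  idx <- cvr_index_map(vol, g, mask)
  list(index = idx, relative = relative_map(idx, mask))
}
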