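#' Parameters for functional connectivity density mapping
#'
#' @param r_thr Pearson correlation threshold; a voxel pair is "connected"
#'   when r strictly exceeds this (default 0.6).
#' @param connectivity Spatial neighborhood for local FCD growth: 6, 18, or
#'   26 (default 26).
#' @param min_sd Minimum temporal standard deviation for a voxel to enter
#'   the correlation computations; quieter voxels get 0 and are excluded as
#'   partners.
#' @return List of class `fcd_params`.
#' @export
fcd_params <- function(r_thr = 0.6, connectivity = 26, min_sd = 1e-8) {
  stopifnot(r_thr > -1, r_thr < 1, connectivity %in% c(6, 18, 26), min_sd >= 0)
  structure(list(r_thr = r_thr, connectivity = connectivity, min_sd = min_sd),
            class = "fcd_params")
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per voxel, the demeaned series is Fourier transformed and the spectral
#' bins with `f_lo < f <= f_hi` (default 0.01–0.08 Hz) are summed. By the
#' convention of the ALFF literature the *amplitude* spectrum (root power)
#' is summed; set `spectrum = "power"` for the squared-magnitude reading.
#' The input must not already be band-passed: ALFF needs the full spectrum.
#'
#' @param vol 4D array, detrended/nuisance-regressed but not band-passed.
#' @param mask 3D binary mask.
#' @param band Band edges in Hz (default `c(0.01, 0.08)`).
#' @param tr Repetition time (s); default from the volume attribute.
#' @param spectrum `"amplitude"` (default) or `"power"`.
#' @return 3D ALFF map (raw; normalize with [relative_map()] for statistics).
#' @export
alff_map <- function(vol, mask, band = c(0.01, 0.08), tr = NULL,
                     spectrum = c("amplitude", "power")) {
  spectrum <- match.arg(spectrum)
  d <- check_vol4d(vol)
  stop_if_not_mask(mask, d)
  if (is.null(tr)) tr <- vol_tr(vol)
  if (band[1] < 0 || band[2] <= band[1] || band[2] > 1 / (2 * tr) + 1e-12)
    stop("invalid ALFF band for this TR", call. = FALSE)
  Y <- vol_to_mat(vol)
  Y <- sweep(Y, 2, colMeans(Y))
  F <- stats::mvfft(Y)
  f <- fft_freqs(d[4], tr)
  # one-sided: take bins with positive folded frequency up to Nyquist once
  half <- seq_len(floor(d[4] / 2) + 1L)
  keep <- half[f[half] > band[1] + 1e-12 & f[half] <= band[2] + 1e-12]
  amp <- Mod(F[keep, , drop = FALSE]) * 2 / d[4]   # single-sided amplitude
  vals <- if (spectrum == "amplitude") colSums(amp) else colSums(amp^2)
  vals[mask == 0] <- 0
  out <- array(vals, dim = d[1:3])
  attr(out, "spacing") <- attr(vol, "spacing")
  attr(out, "metric") <- "alff"
  out
}

# Standardize voxel series inside the mask; returns list(Z, valid, idx)
# where Z is nt x nvalid with unit-norm demeaned columns.
standardize_series <- function(vol, mask, min_sd) {
  d <- dim(vol)
  idx <- which(mask != 0)
  Y <- matrix(vol, nrow = prod(d[1:3]))[idx, , drop = FALSE]  # vox x time
  Y <- Y - rowMeans(Y)
  ss <- sqrt(rowSums(Y^2))
  sd_t <- ss / sqrt(max(1, d[4] - 1))
  valid <- sd_t > min_sd
  Z <- Y[valid, , drop = FALSE] / ss[valid]
  list(Z = Z, idx = idx, valid = valid)
}

#' Global functional connectivity density (gFCD)
#'
#' For every in-mask voxel, the number of other in-mask voxels whose Pearson
#' correlation with it strictly exceeds `r_thr` (default 0.6), anywhere in
#' the brain. Self-correlation is excluded; voxels below the temporal-SD
#' floor get 0 and are excluded as partners.
#'
#' @param vol 4D preprocessed (standard-branch) array.
#' @param mask 3D binary mask.
#' @param params [fcd_params()].
#' @return 3D integer count map.
#' @export
gfcd_map <- function(vol, mask, params = fcd_params()) {
  d <- check_vol4d(vol)
  stop_if_not_mask(mask, d)
  s <- standardize_series(vol, mask, params$min_sd)
  if (nrow(s$Z) < 2) stop("need at least 2 voxels with non-degenerate series",
                          call. = FALSE)
  R <- tcrossprod(s$Z)
  counts <- rowSums(R > params$r_thr) - 1L      # diagonal r = 1 always counted
  vals <- numeric(length(s$idx))
  vals[s$valid] <- counts
  out <- array(0, dim = d[1:3])
  out[s$idx] <- vals
  attr(out, "spacing") <- attr(vol, "spacing")
  attr(out, "metric") <- "gfcd"
  out
}

#' Local functional connectivity density (lFCD)
#'
#' Region growing from each seed voxel: starting at the seed, neighboring
#' voxels (26-connectivity by default) join the cluster when their
#' correlation *with the seed* strictly exceeds `r_thr`, and the front then
#' expands from every accepted voxel. The value is the final cluster size
#' excluding the seed, so lFCD is always a subset count of gFCD.
#'
#' @inheritParams gfcd_map
#' @return 3D integer count map.
#' @export
lfcd_map <- function(vol, mask, params = fcd_params()) {
  d <- check_vol4d(vol)
  stop_if_not_mask(mask, d)
  s <- standardize_series(vol, mask, params$min_sd)
  if (nrow(s$Z) < 2) stop("need at least 2 voxels with non-degenerate series",
                          call. = FALSE)
  dims <- d[1:3]
  # map from linear voxel index -> row of Z (0 if invalid/out of mask)
  zrow <- integer(prod(dims))
  zrow[s$idx[s$valid]] <- seq_len(sum(s$valid))
  R <- tcrossprod(s$Z)                           # nvalid x nvalid
  offs <- neighbor_offsets(params$connectivity)
  coords <- arrayInd(s$idx[s$valid], dims)
  nvalid <- nrow(coords)
  # precompute neighbor z-rows for each valid voxel
  nbr <- vector("list", nvalid)
  for (i in seq_len(nvalid)) {
    p <- sweep(offs, 2, coords[i, ], `+`)
    ok <- p[, 1] >= 1 & p[, 1] <= dims[1] & p[, 2] >= 1 & p[, 2] <= dims[2] &
          p[, 3] >= 1 & p[, 3] <= dims[3]
    lin <- p[ok, 1] + (p[ok, 2] - 1) * dims[1] + (p[ok, 3] - 1) * dims[1] * dims[2]
    zr <- zrow[lin]
    nbr[[i]] <- zr[zr > 0L]
  }
  counts <- integer(nvalid)
  for (seed in seq_len(nvalid)) {
    rs <- R[seed, ]
    inclust <- logical(nvalid)
    inclust[seed] <- TRUE
    front <- seed
    while (length(front)) {
      cand <- unique(unlist(nbr[front], use.names = FALSE))
      cand <- cand[!inclust[cand]]
      accept <- cand[rs[cand] > params$r_thr]
      inclust[accept] <- TRUE
      front <- accept
    }
    counts[seed] <- sum(inclust) - 1L
  }
  vals <- numeric(length(s$idx))
  vals[s$valid] <- counts
  out <- array(0, dim = dims)
  out[s$idx] <- vals
  attr(out, "spacing") <- attr(vol, "spacing")
  attr(out, "metric") <- "lfcd"
  out
}

#' Long-range functional connectivity density (lrFCD)
#'
#' Voxel-wise difference gFCD - lFCD of the two raw count maps; non-negative
#' whenever both maps come from the same data and parameters.
#'
#' @param g Raw gFCD count map.
#' @param l Raw lFCD count map on the same grid.
#' @return 3D count map.
#' @export
lrfcd_map <- function(g, l) {
  if (!identical(dim(g), dim(l))) stop("gFCD and lFCD grids differ", call. = FALSE)
  out <- g - l
  attr(out, "spacing") <- attr(g, "spacing")
  attr(out, "metric") <- "lrfcd"
  out
}
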