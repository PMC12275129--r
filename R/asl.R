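#' Constants of the one-compartment PCASL quantification model
#'
#' @param lambda Brain/blood partition coefficient (mL/g), default 0.9.
#' @param pld Post-labeling delay (ms), default 2025.
#' @param tau Labeling duration (ms), default 1500.
#' @param t1a Longitudinal relaxation time of arterial blood (ms),
#'   default 1650.
#' @param alpha Labeling efficiency (unitless), default 0.85.
#' @return List of class `asl_constants`.
#' @export
asl_constants <- function(lambda = 0.9, pld = 2025, tau = 1500,
                          t1a = 1650, alpha = 0.85) {
  stopifnot(lambda > 0, pld > 0, tau > 0, t1a > 0, alpha > 0, alpha <= 1)
  structure(list(lambda = lambda, pld = pld, tau = tau, t1a = t1a,
                 alpha = alpha), class = "asl_constants")
}

#' Scalar conversion factor of the CBF equation
#'
#' `6000 * lambda * exp(PLD/T1a) / (2 * alpha * (1 - exp(-tau/T1a)))`:
#' multiplied by ΔM/M0 this yields CBF in mL/100 g/min (the 6000 converts
#' mL/g/s to mL/100 g/min). With the default constants the factor is about
#' 1.815e4.
#'
#' @param c [asl_constants()].
#' @return Numeric scalar.
#' @export
cbf_factor <- function(c = asl_constants()) {
  6000 * c$lambda * exp(c$pld / c$t1a) / (2 * c$alpha * (1 - exp(-c$tau / c$t1a)))
}

#' Absolute CBF from a PCASL difference/M0 pair
#'
#' Voxel-wise evaluation of the one-compartment model
#' `CBF = 6000 lambda e^{PLD/T1a} / (2 alpha (1 - e^{-tau/T1a})) * dM/M0`
#' in mL/100 g/min. Negative values (noise) are retained, not clipped; the
#' count of negative in-mask voxels is attached as an attribute.
#'
#' @param dm Perfusion-difference volume (3D array).
#' @param m0 Proton-density volume (3D array), strictly positive in-mask.
#' @param mask 3D binary brain mask.
#' @param constants [asl_constants()].
#' @return 3D CBF map (mL/100 g/min), 0 outside the mask; attribute
#'   `n_negative` counts negative in-mask voxels.
#' @export
quantify_cbf <- function(dm, m0, mask, constants = asl_constants()) {
  if (!identical(dim(dm), dim(m0))) stop("dM and M0 grids differ", call. = FALSE)
  stop_if_not_mask(mask, dim(dm))
  inside <- mask != 0
  nbad <- sum(m0[inside] <= 0)
  if (nbad > 0)
    stop(nbad, " in-mask voxel(s) have non-positive M0", call. = FALSE)
  out <- array(0, dim = dim(dm))
  out[inside] <- cbf_factor(constants) * dm[inside] / m0[inside]
  attr(out, "spacing") <- attr(dm, "spacing")
  attr(out, "metric") <- "cbf"
  attr(out, "n_negative") <- sum(out[inside] < 0)
  out
}

#' Whole-brain mean CBF
#'
#' Mean of the absolute CBF map over the brain mask (mL/100 g/min); the
#' non-normalized quantity compared across groups separately from the
#' relative maps.
#'
#' @param m 3D CBF map.
#' @param mask 3D binary mask.
#' @return Scalar mean.
#' @export
global_mean_cbf <- function(m, mask) {
  stop_if_not_mask(mask, dim(m))
  mean(m[mask != 0])
}

#' Normalize a CBF map by the subject's global mean
#'
#' Delegates to [relative_map()].
#' @inheritParams global_mean_cbf
#' @return Normalized 3D map.
#' @export
normalize_cbf <- function(m, mask) relative_map(m, mask)
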