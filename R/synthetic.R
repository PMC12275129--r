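# Synthetic phantoms with known ground truth. Every generator is
# deterministic given its spec and seed; randomness is drawn from a
# locally-scoped RNG so callers' streams are untouched.

# Band-limited unit-variance signal: white noise, boxcar-filtered in the
# Fourier domain to (f_lo, f_hi], rescaled to SD 1.
bandlimited_signal <- function(nt, tr, f_lo, f_hi) {
  x <- stats::rnorm(nt)
  f <- fft_freqs(nt, tr)
  keep <- f > f_lo + 1e-12 & f <= f_hi + 1e-12
  keep[1] <- FALSE
  F <- stats::fft(x)
  F[!keep] <- 0
  y <- Re(stats::fft(F, inverse = TRUE)) / nt
  s <- stats::sd(y)
  if (s < 1e-12) stop("degenerate band for this nt/TR", call. = FALSE)
  y / s
}

#' Specification of a synthetic BOLD phantom
#'
#' @param shape Grid `c(nx, ny, nz, nt)`; spatial dims >= 2, nt >= 64.
#' @param tr Repetition time (s), default 2.
#' @param band Support of the shared global fluctuation, Hz
#'   (default `c(0, 0.1164)`, the CVR analysis band).
#' @param gain Per-voxel CVR gain: scalar or 3D array (unitless coupling to
#'   the global signal).
#' @param clusters List of voxel-coordinate matrices (rows = `(i,j,k)`);
#'   each cluster shares one latent signal. Clusters must be disjoint.
#' @param pairs List of 2-row coordinate matrices: distant voxel pairs
#'   sharing a latent but not spatially adjacent.
#' @param latent_amp Amplitude of cluster/pair latents.
#' @param latent_band Band of the latents, Hz (default `c(0.01, 0.08)` so
#'   they survive the standard-branch filter).
#' @param sinusoids List of `list(freq, amp, voxels)` entries; `voxels` is a
#'   coordinate matrix receiving `amp * sin(2 pi freq t)`.
#' @param noise_sd White-noise SD added to every voxel.
#' @param baseline Constant signal offset (default 100).
#' @param seed Integer seed.
#' @return List of class `bold_phantom_spec`.
#' @export
bold_phantom_spec <- function(shape = c(8, 8, 4, 120), tr = 2,
                              band = c(0, 0.1164), gain = 1,
                              clusters = list(), pairs = list(),
                              latent_amp = 1, latent_band = c(0.01, 0.08),
                              sinusoids = list(), noise_sd = 0.1,
                              baseline = 100, seed = 1) {
  if (any(shape[1:3] < 2)) stop("spatial dims must be >= 2", call. = FALSE)
  if (shape[4] < 64) stop("nt must be >= 64 so band edges are resolvable",
                          call. = FALSE)
  if (is.array(gain) && !identical(dim(gain), as.integer(shape[1:3])))
    stop("gain map shape mismatch", call. = FALSE)
  if (!all(is.finite(gain))) stop("gains must be finite", call. = FALSE)
  if (length(clusters) > 1) {
    lin <- lapply(clusters, function(cl)
      cl[, 1] + (cl[, 2] - 1) * shape[1] + (cl[, 3] - 1) * shape[1] * shape[2])
    if (anyDuplicated(unlist(lin))) stop("clusters must be disjoint", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), tr = tr, band = band, gain = gain,
                 clusters = clusters, pairs = pairs, latent_amp = latent_amp,
                 latent_band = latent_band, sinusoids = sinusoids,
                 noise_sd = noise_sd, baseline = baseline, seed = seed),
            class = "bold_phantom_spec")
}

coords_to_lin <- function(cl, dims) {
  cl <- matrix(as.integer(cl), ncol = 3)
  cl[, 1] + (cl[, 2] - 1L) * dims[1] + (cl[, 3] - 1L) * dims[1] * dims[2]
}

#' Generate a synthetic BOLD series with known CVR/FCD/ALFF ground truth
#'
#' Each voxel's series is
#' `baseline + g_v G(t) + cluster/pair latents + sinusoids + noise` where
#' `G(t)` is a shared band-limited global fluctuation of unit variance.
#' Motion parameters are smooth low-amplitude random walks.
#'
#' @param spec A [bold_phantom_spec()].
#' @return List: `vol` (4D array with spacing/TR attributes), `mask`
#'   (all-foreground 3D mask), `motion` (nt x 6 matrix), and `truth`
#'   (gain map, cluster/pair memberships, sinusoid table, global signal).
#' @export
make_bold_phantom <- function(spec) {
  stopifnot(inherits(spec, "bold_phantom_spec"))
  d <- spec$shape
  with_seed(split_seed(spec$seed, 1L), {
    G <- bandlimited_signal(d[4], spec$tr, spec$band[1], spec$band[2])
    nvox <- prod(d[1:3])
    gain <- if (is.array(spec$gain)) as.vector(spec$gain) else rep(spec$gain, nvox)
    Y <- outer(gain, G)                       # vox x time
    for (cl in spec$clusters) {
      lat <- spec$latent_amp *
        bandlimited_signal(d[4], spec$tr, spec$latent_band[1], spec$latent_band[2])
      lin <- coords_to_lin(cl, d)
      Y[lin, ] <- Y[lin, ] + rep(lat, each = length(lin))
    }
    for (pr in spec$pairs) {
      lat <- spec$latent_amp *
        bandlimited_signal(d[4], spec$tr, spec$latent_band[1], spec$latent_band[2])
      lin <- coords_to_lin(pr, d)
      Y[lin, ] <- Y[lin, ] + rep(lat, each = length(lin))
    }
    sin_tab <- NULL
    tt <- (seq_len(d[4]) - 1) * spec$tr
    for (sn in spec$sinusoids) {
      lin <- coords_to_lin(sn$voxels, d)
      Y[lin, ] <- Y[lin, ] + rep(sn$amp * sin(2 * pi * sn$freq * tt),
                                 each = length(lin))
      sin_tab <- rbind(sin_tab, data.frame(freq = sn$freq, amp = sn$amp,
                                           n_vox = length(lin)))
    }
    if (spec$noise_sd > 0)
      Y <- Y + matrix(stats::rnorm(length(Y), sd = spec$noise_sd), nrow = nvox)
    Y <- Y + spec$baseline
    vol <- array(Y, dim = d)
    attr(vol, "spacing") <- c(3, 3, 3)
    attr(vol, "tr") <- spec$tr
    # smooth low-amplitude random walks for the 6 rigid-body parameters
    motion <- sapply(1:6, function(j) {
      amp <- if (j <= 3) 0.05 else 0.001      # mm vs radians
      w <- cumsum(stats::rnorm(d[4], sd = amp))
      stats::filter(c(w[1], w[1], w, w[d[4]], w[d[4]]),
                    rep(1 / 5, 5), sides = 2)[3:(d[4] + 2)]
    })
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    mask <- array(1L, dim = d[1:3])
    list(vol = vol, mask = mask, motion = motion,
         truth = list(gain = array(gain, dim = d[1:3]),
                      clusters = spec$clusters, pairs = spec$pairs,
                      sinusoids = sin_tab, global_signal = G))
  })
}

#' Specification of a synthetic ASL phantom
#'
#' @param shape Spatial grid `c(nx, ny, nz)`.
#' @param cbf True CBF, mL/100 g/min: scalar or 3D array, non-negative.
#' @param m0 Proton-density level: scalar or 3D array, positive in-mask.
#' @param noise_sd Additive noise SD on the difference image.
#' @param constants [asl_constants()].
#' @param seed Integer seed.
#' @return List of class `asl_phantom_spec`.
#' @export
asl_phantom_spec <- function(shape = c(16, 16, 8), cbf = 60, m0 = 1000,
                             noise_sd = 0, constants = asl_constants(),
                             seed = 1) {
  if (any(cbf < 0)) stop("true CBF must be non-negative", call. = FALSE)
  if (any(m0 <= 0)) stop("M0 must be positive", call. = FALSE)
  structure(list(shape = as.integer(shape), cbf = cbf, m0 = m0,
                 noise_sd = noise_sd, constants = constants, seed = seed),
            class = "asl_phantom_spec")
}

#' Forward-model a PCASL difference/M0 pair from a known CBF map
#'
#' Inverts the one-compartment quantification:
#' `dM = CBF_true * M0 / factor + noise` with the same constant factor used
#' by [quantify_cbf()], so the noise-free round trip closes exactly.
#'
#' @param spec An [asl_phantom_spec()].
#' @return List: `dm`, `m0` (3D arrays), `mask`, `cbf_true`.
#' @export
make_asl_phantom <- function(spec) {
  stopifnot(inherits(spec, "asl_phantom_spec"))
  d <- spec$shape
  expand <- function(x) if (is.array(x)) x else array(x, dim = d)
  cbf <- expand(spec$cbf); m0 <- expand(spec$m0)
  dm <- cbf * m0 / cbf_factor(spec$constants)
  if (spec$noise_sd > 0)
    dm <- dm + with_seed(split_seed(spec$seed, 2L),
                         array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d))
  mask <- array(1L, dim = d)
  list(dm = dm, m0 = m0, mask = mask, cbf_true = cbf)
}

#' Specification of a synthetic bright-vessel phantom
#'
#' @param shape Spatial grid `c(nx, ny, nz)`.
#' @param spacing Voxel spacing, mm (default 0.86 isotropic, the working
#'   resolution of the vessel pipeline).
#' @param cylinders List of `list(start, end, radius, intensity)`: axis
#'   endpoints in mm (voxel (1,1,1) center is at (0,0,0) mm), radius in mm
#'   (> spacing/2), intensity in arbitrary units.
#' @param background Background intensity.
#' @param noise_sd Additive white-noise SD.
#' @param seed Integer seed.
#' @return List of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(shape = c(40, 40, 40), spacing = rep(0.86, 3),
                                cylinders = list(), background = 10,
                                noise_sd = 0, seed = 1) {
  fov <- (shape - 1) * spacing
  for (cy in cylinders) {
    if (cy$radius <= max(spacing) / 2)
      stop("cylinder radius must exceed half the voxel spacing", call. = FALSE)
    if (any(cy$start < -spacing) || any(cy$start > fov + spacing) ||
        any(cy$end < -spacing) || any(cy$end > fov + spacing))
      stop("cylinder endpoints must lie within the grid", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), spacing = spacing,
                 cylinders = cylinders, background = background,
                 noise_sd = noise_sd, seed = seed),
            class = "vessel_phantom_spec")
}

# distance from points (N x 3, mm) to the segment a-b (mm)
point_segment_dist <- function(p, a, b) {
  v <- b - a
  l2 <- sum(v^2)
  if (l2 < 1e-12) return(sqrt(rowSums(sweep(p, 2, a)^2)))
  tt <- pmin(1, pmax(0, (sweep(p, 2, a) %*% v) / l2))
  proj <- sweep(tt %*% t(v), 2, a, `+`)
  sqrt(rowSums((p - proj)^2))
}

#' Generate a bright-tube volume with known radii
#'
#' Voxels inside any cylinder take the cylinder intensity; rim voxels are
#' anti-aliased by the partial-volume fraction estimated from a 3x3x3
#' supersampled occupancy, which makes sub-voxel radius recovery
#' meaningful. Overlapping cylinders are allowed but flagged in the truth
#' record.
#'
#' @param spec A [vessel_phantom_spec()].
#' @return List: `vol` (3D array with spacing attribute), `truth`
#'   (per-cylinder radius/axis table, overlap flag).
#' @export
make_vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  nvox <- prod(d)
  ctr <- arrayInd(seq_len(nvox), d)
  ctr_mm <- sweep(ctr - 1, 2, sp, `*`)
  subs <- as.matrix(expand.grid(s1 = c(-1, 0, 1) / 3, s2 = c(-1, 0, 1) / 3,
                                s3 = c(-1, 0, 1) / 3))
  occ_any <- matrix(0, nrow = nvox, ncol = max(1L, length(spec$cylinders)))
  vol <- array(spec$background, dim = d)
  for (ci in seq_along(spec$cylinders)) {
    cy <- spec$cylinders[[ci]]
    frac <- numeric(nvox)
    for (si in seq_len(nrow(subs))) {
      pts <- ctr_mm + matrix(subs[si, ] * sp, nrow = nvox, ncol = 3, byrow = TRUE)
      frac <- frac + (point_segment_dist(pts, cy$start, cy$end) <= cy$radius)
    }
    frac <- frac / nrow(subs)
    occ_any[, ci] <- frac
    vol <- vol + array(frac * (cy$intensity - spec$background), dim = d)
  }
  overlap <- length(spec$cylinders) >= 2 &&
    any(rowSums(occ_any > 0.5) > 1)
  if (spec$noise_sd > 0)
    vol <- vol + with_seed(split_seed(spec$seed, 3L),
                           array(stats::rnorm(nvox, sd = spec$noise_sd), dim = d))
  attr(vol, "spacing") <- sp
  truth <- data.frame(
    cylinder = seq_along(spec$cylinders),
    radius_mm = vapply(spec$cylinders, function(cy) cy$radius, 0),
    length_mm = vapply(spec$cylinders,
                       function(cy) sqrt(sum((cy$end - cy$start)^2)), 0))
  list(vol = vol, truth = list(radii = truth, overlap = overlap))
}

#' Specification of a synthetic three-group cohort
#'
#' Emulates a case-control design with healthy controls (HC), Parkinson's
#' disease with normal cognition (PD-NC) and with mild cognitive impairment
#' (PD-MCI): demographics, clinical covariates, 12 cognitive test scores,
#' and ROI-level imaging-metric columns with planted group effects.
#'
#' @param n_hc,n_pdnc,n_pdmci Group sizes (default 48/34/25); each >= 3.
#' @param metrics Character vector of ROI-metric column names to simulate.
#' @param effects Named list: metric name -> numeric length-3 vector of
#'   group median shifts in SD units, order (HC, PD-NC, PD-MCI).
#' @param target_rho Optional `list(metric, score, group, rho)`: plant a
#'   Spearman correlation of `rho` between the metric and the cognitive
#'   score within one group via a Gaussian copula.
#' @param rater_sd Measurement-noise SD (same units as the metric) for the
#'   duplicate rater-2 columns; applied to metrics listed in `rater_vars`.
#' @param rater_vars Metrics receiving `<name>_rater2` duplicate columns.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 48, n_pdnc = 34, n_pdmci = 25,
                        metrics = c("cvr_roi1", "cvr_roi2"),
                        effects = list(), target_rho = NULL,
                        rater_sd = 0, rater_vars = character(), seed = 1) {
  if (min(n_hc, n_pdnc, n_pdmci) < 3) stop("group sizes must be >= 3", call. = FALSE)
  if (!is.null(target_rho) && abs(target_rho$rho) > 1)
    stop("|target correlation| must be <= 1", call. = FALSE)
  structure(list(n_hc = n_hc, n_pdnc = n_pdnc, n_pdmci = n_pdmci,
                 metrics = metrics, effects = effects,
                 target_rho = target_rho, rater_sd = rater_sd,
                 rater_vars = rater_vars, seed = seed),
            class = "cohort_spec")
}

#' Names of the simulated cognitive test battery
#' @return Character vector of the 12 test score columns.
#' @export
cognitive_tests <- function() {
  c("MMSE", "AVLT", "CFT_delay", "CFT", "CDT", "AFT",
    "SDMT", "TMT_A", "TMT_B", "CWT_time", "CWT_right", "BNT")
}

#' Generate a synthetic cohort table with planted effects
#'
#' Group labels, covariates (age, sex, education, UPDRS-III, GDS), the
#' 12-test cognitive battery, and ROI-metric values with planted median
#' shifts. A requested Spearman correlation between one metric and one
#' score within one group is realized through a Gaussian copula (latent
#' Pearson `2 sin(pi rho / 6)`), which survives the monotone mapping onto
#' the score scale. Rater-2 duplicate columns are rater-1 plus Gaussian
#' noise.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame, one row per subject.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(split_seed(spec$seed, 4L), {
    n <- c(HC = spec$n_hc, `PD-NC` = spec$n_pdnc, `PD-MCI` = spec$n_pdmci)
    N <- sum(n)
    group <- factor(rep(names(n), n), levels = names(n))
    df <- data.frame(
      subject = sprintf("S%03d", seq_len(N)),
      group = group,
      age = round(stats::rnorm(N, mean = c(64, 63, 68)[as.integer(group)], sd = 8), 1),
      sex = sample(c("M", "F"), N, replace = TRUE),
      education = round(pmax(0, stats::rnorm(N, 10, 3)), 0),
      updrs3 = ifelse(group == "HC", 0,
                      round(pmax(0, stats::rnorm(N, c(0, 15, 20)[as.integer(group)], 7)))),
      gds = round(pmax(0, stats::rnorm(N, c(6, 9, 12)[as.integer(group)], 5))),
      stringsAsFactors = FALSE)
    # cognitive battery: latent normals, shifted for PD-MCI, mapped to score-like scales
    score_means <- c(MMSE = 29, AVLT = 31, CFT_delay = 16, CFT = 31, CDT = 9,
                     AFT = 19, SDMT = 42, TMT_A = 55, TMT_B = 125,
                     CWT_time = 75, CWT_right = 47, BNT = 26)
    score_sds <- c(MMSE = 1.4, AVLT = 9, CFT_delay = 6, CFT = 4, CDT = 0.8,
                   AFT = 5.5, SDMT = 10, TMT_A = 20, TMT_B = 40,
                   CWT_time = 20, CWT_right = 3, BNT = 2.5)
    timed <- c("TMT_A", "TMT_B", "CWT_time")  # higher = worse
    latents <- list()
    for (ts in cognitive_tests()) {
      z <- stats::rnorm(N)
      shift <- ifelse(group == "PD-MCI", if (ts %in% timed) 1.2 else -1.2, 0)
      latents[[ts]] <- z + shift
    }
    # metric columns with planted median shifts (SD units)
    for (mname in spec$metrics) {
      eff <- spec$effects[[mname]]
      if (is.null(eff)) eff <- c(0, 0, 0)
      zm <- stats::rnorm(N)
      if (!is.null(spec$target_rho) && spec$target_rho$metric == mname) {
        tr <- spec$target_rho
        rho_p <- 2 * sin(pi * tr$rho / 6)
        sel <- group == tr$group
        S <- matrix(c(1, rho_p, rho_p, 1), 2)
        ee <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (any(ee <= 0)) stop("infeasible correlation structure", call. = FALSE)
        zz <- MASS::mvrnorm(sum(sel), mu = c(0, 0), Sigma = S)
        zm[sel] <- zz[, 1]
        latents[[tr$score]][sel] <- zz[, 2]
      }
      df[[mname]] <- zm + eff[as.integer(group)]
      if (mname %in% spec$rater_vars)
        df[[paste0(mname, "_rater2")]] <- df[[mname]] +
          stats::rnorm(N, sd = spec$rater_sd)
    }
    for (ts in cognitive_tests())
      df[[ts]] <- round(score_means[[ts]] + score_sds[[ts]] * latents[[ts]], 1)
    df
  })
}

#' Generate a contiguous random parcellation of a grid
#'
#' Labels 1..n_labels tile the foreground by multi-source flood fill
#' (6-connectivity) from randomly placed seeds, so every region is
#' contiguous and the labels plus background partition the grid exactly.
#'
#' @param shape Spatial grid `c(nx, ny, nz)`.
#' @param n_labels Number of regions; must not exceed the foreground size.
#' @param seed Integer seed.
#' @param mask Optional 3D foreground mask (default: whole grid).
#' @return List: `labels` (3D integer array, 0 = background) and `table`
#'   (data.frame label/name).
#' @export
make_atlas <- function(shape, n_labels, seed = 1, mask = NULL) {
  shape <- as.integer(shape)
  if (is.null(mask)) mask <- array(1L, dim = shape)
  fg <- which(mask != 0)
  if (n_labels > length(fg)) stop("more labels than foreground voxels", call. = FALSE)
  lab <- array(0L, dim = shape)
  with_seed(split_seed(seed, 5L), {
    seeds <- sample(fg, n_labels)
    lab[seeds] <- seq_len(n_labels)
    offs <- neighbor_offsets(6)
    repeat {
      unl <- which(mask != 0 & lab == 0L)
      if (!length(unl)) break
      coords <- arrayInd(unl, shape)
      newlab <- integer(length(unl))
      for (o in seq_len(nrow(offs))) {
        p <- sweep(coords, 2, offs[o, ], `+`)
        ok <- p[, 1] >= 1 & p[, 1] <= shape[1] & p[, 2] >= 1 & p[, 2] <= shape[2] &
              p[, 3] >= 1 & p[, 3] <= shape[3]
        lin <- p[ok, 1] + (p[ok, 2] - 1L) * shape[1] +
               (p[ok, 3] - 1L) * shape[1] * shape[2]
        cand <- integer(length(unl)); cand[ok] <- lab[lin]
        newlab[newlab == 0L & cand > 0L] <- cand[newlab == 0L & cand > 0L]
      }
      if (!any(newlab > 0L)) {  # disconnected foreground: reseed one voxel
        newlab[1] <- lab[seeds[1]]
        lab[unl[1]] <- newlab[1]
        next
      }
      lab[unl[newlab > 0L]] <- newlab[newlab > 0L]
    }
  })
  list(labels = lab,
       table = data.frame(label = seq_len(n_labels),
                          name = sprintf("ROI_%02d", seq_len(n_labels))))
}
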