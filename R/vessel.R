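# Arterial morphology from bright-vessel volumes: multiscale Hessian
# enhancement, region growing, topological centerline extraction, and
# distance-based radius sampling averaged over >= 5 positions per segment.

#' Parameters for multiscale Hessian vessel enhancement
#'
#' @param scales Gaussian scales in mm (default 6 steps over 0.5–3.0 mm,
#'   bracketing arterial radii of 1–2.5 mm).
#' @param a Plate/line sensitivity (Frangi alpha, default 0.5).
#' @param b Blobness sensitivity (Frangi beta, default 0.5).
#' @param c Structureness sensitivity; `NULL` (default) uses half the
#'   maximum Hessian norm at each scale.
#' @param bright If `TRUE` (default) enhance bright tubes on dark
#'   background.
#' @return List of class `vesselness_params`.
#' @export
vesselness_params <- function(scales = seq(0.5, 3.0, length.out = 6),
                              a = 0.5, b = 0.5, c = NULL, bright = TRUE) {
  stopifnot(all(scales > 0), !is.unsorted(scales), a > 0, b > 0,
            is.null(c) || c > 0)
  structure(list(scales = scales, a = a, b = b, c = c, bright = bright),
            class = "vesselness_params")
}

#' Resample a volume to isotropic resolution
#'
#' Trilinear interpolation onto an isotropic grid (default 0.86 mm), the
#' working resolution of the vessel pipeline. Linear fields are reproduced
#' exactly; the field of view is preserved to within one voxel.
#'
#' @param vol 3D array with a `spacing` attribute, or pass `spacing`.
#' @param target_mm Target isotropic spacing in mm (default 0.86).
#' @param spacing Source spacing in mm (length 3).
#' @return Resampled 3D array with updated `spacing`.
#' @export
interpolate_isotropic <- function(vol, target_mm = 0.86, spacing = NULL) {
  if (is.null(spacing)) spacing <- vol_spacing(vol)
  d <- dim(vol)
  fov <- (d - 1) * spacing
  nd <- pmax(2L, as.integer(floor(fov / target_mm)) + 1L)
  # target voxel centers in source voxel coordinates (1-based, fractional)
  gx <- (seq_len(nd[1]) - 1) * target_mm / spacing[1] + 1
  gy <- (seq_len(nd[2]) - 1) * target_mm / spacing[2] + 1
  gz <- (seq_len(nd[3]) - 1) * target_mm / spacing[3] + 1
  clampf <- function(g, n) pmin(pmax(g, 1), n)
  gx <- clampf(gx, d[1]); gy <- clampf(gy, d[2]); gz <- clampf(gz, d[3])
  x0 <- pmin(floor(gx), d[1] - 1); y0 <- pmin(floor(gy), d[2] - 1)
  z0 <- pmin(floor(gz), d[3] - 1)
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  out <- array(0, dim = nd)
  X0 <- as.integer(x0); Y0 <- as.integer(y0); Z0 <- as.integer(z0)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- outer(outer(if (dx) fx else 1 - fx, if (dy) fy else 1 - fy),
               if (dz) fz else 1 - fz)
    out <- out + w * vol[X0 + dx, Y0 + dy, Z0 + dz, drop = FALSE]
  }
  attr(out, "spacing") <- rep(target_mm, 3)
  out
}

# shift a 3D array by (dx,dy,dz) with replicate padding
shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# Eigenvalues of a field of symmetric 3x3 matrices (vectors of entries),
# via the trigonometric closed form; returns n x 3 matrix, unsorted.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-30
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detB <- b11 * b22 * b33 + 2 * b12 * b13 * b23 -
    b11 * b23^2 - b22 * b13^2 - b33 * b12^2
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  cbind(e1, e2, e3)
}

#' Multiscale Frangi vesselness
#'
#' At each scale the volume is Gaussian-smoothed, the Hessian is formed by
#' central differences (scale-normalized by sigma^2), its eigenvalues are
#' sorted by magnitude `|l1| <= |l2| <= |l3|`, and the Frangi tube measure
#' combines the plate/line ratio `|l2|/|l3|`, the blobness ratio
#' `|l1|/sqrt(|l2 l3|)` and the structureness norm. Bright tubes require
#' `l2, l3 < 0`. The map is the maximum response over scales, in [0, 1].
#'
#' @param vol 3D array with a `spacing` attribute, or pass `spacing`.
#' @param params [vesselness_params()].
#' @param spacing Voxel spacing in mm.
#' @return 3D vesselness map in `[0, 1]`.
#' @export
hessian_vesselness <- function(vol, params = vesselness_params(),
                               spacing = NULL) {
  if (is.null(spacing)) spacing <- vol_spacing(vol)
  d <- dim(vol)
  v <- array(as.numeric(vol), dim = d)
  best <- array(0, dim = d)
  for (sg in params$scales) {
    ks <- lapply(sg / spacing, gauss_kernel_1d)
    sm <- v
    for (ax in 1:3) sm <- conv_axis(sm, ks[[ax]], ax)
    h <- spacing
    d2 <- function(ax) {
      sh <- switch(ax, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
      (shift3(sm, sh[1], sh[2], sh[3]) + shift3(sm, -sh[1], -sh[2], -sh[3]) -
         2 * sm) / h[ax]^2
    }
    dmix <- function(ax1, ax2) {
      s1 <- diag(3)[ax1, ]; s2 <- diag(3)[ax2, ]
      (shift3(sm, s1[1] + s2[1], s1[2] + s2[2], s1[3] + s2[3]) -
         shift3(sm, s1[1] - s2[1], s1[2] - s2[2], s1[3] - s2[3]) -
         shift3(sm, s2[1] - s1[1], s2[2] - s1[2], s2[3] - s1[3]) +
         shift3(sm, -s1[1] - s2[1], -s1[2] - s2[2], -s1[3] - s2[3])) /
        (4 * h[ax1] * h[ax2])
    }
    s2n <- sg^2    # gamma = 2 scale normalization
    E <- sym3_eigenvalues(s2n * d2(1), s2n * d2(2), s2n * d2(3),
                          s2n * dmix(1, 2), s2n * dmix(1, 3), s2n * dmix(2, 3))
    A <- abs(E)
    imax <- max.col(A, ties.method = "first")
    imin <- max.col(-A, ties.method = "last")
    imin[imin == imax] <- ((imax[imin == imax]) %% 3L) + 1L
    imid <- 6L - imax - imin
    n <- nrow(E)
    l1 <- E[cbind(seq_len(n), imin)]
    l2 <- E[cbind(seq_len(n), imid)]
    l3 <- E[cbind(seq_len(n), imax)]
    if (!params$bright) { l2 <- -l2; l3 <- -l3 }
    Ra <- abs(l2) / pmax(abs(l3), 1e-30)
    Rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-30)
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- if (is.null(params$c)) max(S) / 2 else params$c
    if (cc < 1e-30) next
    resp <- (1 - exp(-Ra^2 / (2 * params$a^2))) *
      exp(-Rb^2 / (2 * params$b^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    resp[l2 > 0 | l3 > 0] <- 0
    best <- pmax(best, array(resp, dim = d))
  }
  attr(best, "spacing") <- spacing
  best
}

# connected components of a logical 3D array (given connectivity)
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lin_offs <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]
  lab <- array(0L, dim = d)
  fg <- which(mask)
  inmask <- array(FALSE, dim = d); inmask[fg] <- TRUE
  coords <- arrayInd(fg, d)
  # interior test avoids per-voxel bounds checks for the common case
  cur <- 0L
  for (v in fg) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v; lab[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pc <- arrayInd(p, d)
      nb <- sweep(offs, 2, pc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
      nl <- nl[inmask[nl] & lab[nl] == 0L]
      if (length(nl)) { lab[nl] <- cur; queue <- c(queue, nl) }
    }
  }
  lab
}

#' Grow a vessel mask from high-vesselness seeds
#'
#' Seeds are voxels with vesselness at least `seed_thr` times the map
#' maximum; the mask is the flood fill (26-connectivity) of voxels at least
#' `grow_thr` times the maximum, restricted to components containing a
#' seed. The scale-space response is wider than the vessel lumen, so when
#' the underlying intensity image is supplied the grown mask is refined to
#' the full-width-at-half-maximum contour: voxels brighter than halfway
#' between the background level (median outside the grown region) and the
#' vessel level (median over seeds). This recovers the lumen boundary to
#' sub-voxel accuracy on partial-volume rims.
#'
#' @param vness 3D vesselness map.
#' @param seed_thr Seed threshold as a fraction of the maximum
#'   (default 0.5).
#' @param grow_thr Growth threshold as a fraction of the maximum
#'   (default 0.15); must satisfy `0 < grow_thr <= seed_thr <= 1`.
#' @param intensity Optional 3D intensity volume (same grid) for
#'   half-maximum refinement.
#' @param intensity_frac Refinement level between background (0) and vessel
#'   (1) intensity; default 0.5 (half maximum).
#' @return Logical 3D mask.
#' @export
region_grow_vessels <- function(vness, seed_thr = 0.5, grow_thr = 0.15,
                                intensity = NULL, intensity_frac = 0.5) {
  stopifnot(grow_thr > 0, grow_thr <= seed_thr, seed_thr <= 1)
  mx <- max(vness)
  if (mx <= 0) { warning("no seeds: vesselness map is empty");
    out <- array(FALSE, dim = dim(vness))
    attr(out, "spacing") <- attr(vness, "spacing"); return(out) }
  grow <- vness >= grow_thr * mx
  lab <- label_components(grow, 26)
  seeds <- vness >= seed_thr * mx
  seed_labs <- unique(lab[seeds])
  seed_labs <- seed_labs[seed_labs > 0L]
  keep <- array(lab %in% seed_labs, dim = dim(vness))
  if (!is.null(intensity)) {
    if (!identical(dim(intensity), dim(vness)))
      stop("intensity grid must match vesselness grid", call. = FALSE)
    bg <- stats::median(intensity[!keep])
    # rim voxels dilute the median for thin tubes; a high quantile tracks
    # the true lumen intensity
    lvl <- stats::quantile(intensity[seeds & keep], 0.9, names = FALSE)
    thr <- bg + intensity_frac * (lvl - bg)
    refined <- keep & intensity >= thr
    # connectivity may fragment after refinement: keep seeded components
    lab2 <- label_components(refined, 26)
    sl2 <- unique(lab2[seeds & refined]); sl2 <- sl2[sl2 > 0L]
    keep <- array(lab2 %in% sl2, dim = dim(vness))
  }
  attr(keep, "spacing") <- attr(vness, "spacing")
  keep
}

# --- topological thinning ------------------------------------------------

# 26-neighborhood object connectivity / 6-neighborhood background
# connectivity simple-point test on a 3x3x3 patch (center assumed object).
.n26_offs <- NULL
.n6_offs <- NULL

# count connected components among 'cells' (linear idx in 3x3x3 patch)
patch_components <- function(occupied, offsets) {
  idx <- which(occupied)
  if (!length(idx)) return(0L)
  seen <- logical(27)
  comps <- 0L
  coords <- arrayInd(1:27, c(3, 3, 3))
  for (s in idx) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pc <- coords[p, ]
      nb <- sweep(offsets, 2, pc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= 3 & nb[, 2] >= 1 & nb[, 2] <= 3 &
            nb[, 3] >= 1 & nb[, 3] <= 3
      nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * 3L + (nb[ok, 3] - 1L) * 9L
      nl <- nl[occupied[nl] & !seen[nl]]
      if (length(nl)) { seen[nl] <- TRUE; queue <- c(queue, nl) }
    }
  }
  comps
}

is_simple_point <- function(patch) {
  # patch: logical length 27, center = index 14
  obj <- patch; obj[14] <- FALSE
  if (!any(obj)) return(FALSE)                  # isolated point: keep
  if (patch_components(obj, neighbor_offsets(26)) != 1L) return(FALSE)
  # background 6-components within the 18-neighborhood, 6-adjacent to center
  bg <- !patch; bg[14] <- FALSE
  coords <- arrayInd(1:27, c(3, 3, 3))
  aoff <- abs(sweep(coords, 2, c(2, 2, 2)))
  n18 <- rowSums(aoff) <= 2 & rowSums(aoff) >= 1   # exclude corners and center
  bg18 <- bg & n18
  if (!any(bg18)) return(FALSE)
  # count 6-connected bg components in N18 that touch the center 6-face
  comps <- 0L
  seen <- logical(27)
  offs6 <- neighbor_offsets(6)
  face <- which(rowSums(abs(sweep(coords, 2, c(2, 2, 2)))) == 1)
  for (s in which(bg18)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE
    members <- s
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pc <- coords[p, ]
      nb <- sweep(offs6, 2, pc, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= 3 & nb[, 2] >= 1 & nb[, 2] <= 3 &
            nb[, 3] >= 1 & nb[, 3] <= 3
      nl <- nb[ok, 1] + (nb[ok, 2] - 1L) * 3L + (nb[ok, 3] - 1L) * 9L
      nl <- nl[bg18[nl] & !seen[nl]]
      if (length(nl)) { seen[nl] <- TRUE; queue <- c(queue, nl); members <- c(members, nl) }
    }
    if (any(members %in% face)) comps <- comps + 1L
  }
  comps == 1L
}

get_patch <- function(mask, p, d) {
  # logical length-27 patch around voxel p (arrayInd row), FALSE outside grid
  out <- logical(27)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    x <- p[1] + dx; y <- p[2] + dy; z <- p[3] + dz
    if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3])
      out[k] <- mask[x, y, z]
  }
  out
}

#' Extract centerlines from a vessel mask by 3D topological thinning
#'
#' Iteratively deletes simple border voxels (26-connectivity object,
#' 6-connectivity background) while preserving curve endpoints, leaving a
#' one-voxel-wide skeleton. The skeleton is split into branches at junction
#' voxels (more than 2 skeleton neighbors) and at sharp corners (direction
#' change above `corner_deg` between 5-point chords); each branch is ordered
#' end-to-end and converted to mm coordinates.
#'
#' @param mask Logical 3D vessel mask with a `spacing` attribute.
#' @param spacing Voxel spacing, mm.
#' @param corner_deg Corner-splitting angle threshold in degrees
#'   (default 60).
#' @param min_branch Thinning leaves short spurs where the tube surface is
#'   rough; terminal branches with fewer points than this are pruned when
#'   longer segments exist (default 4).
#' @return List of class `centerline_set`: `segments` (list of mm point
#'   matrices), `ids`, `degenerate` flag.
#' @export
extract_centerline <- function(mask, spacing = NULL, corner_deg = 60,
                               min_branch = 4) {
  if (is.null(spacing)) spacing <- vol_spacing(mask)
  d <- dim(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sk <- array(as.logical(mask), dim = d)
  dirs <- neighbor_offsets(6)
  repeat {
    removed <- 0L
    for (dd in seq_len(nrow(dirs))) {
      cand <- which(sk)
      if (!length(cand)) break
      coords <- arrayInd(cand, d)
      nb <- sweep(coords, 2, dirs[dd, ], `+`)
      outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
                 nb[, 3] < 1 | nb[, 3] > d[3]
      border <- outside
      inb <- !outside
      if (any(inb)) {
        lin <- nb[inb, 1] + (nb[inb, 2] - 1L) * d[1] + (nb[inb, 3] - 1L) * d[1] * d[2]
        border[inb] <- !sk[lin]
      }
      for (i in which(border)) {
        p <- coords[i, ]
        patch <- get_patch(sk, p, d)
        nnb <- sum(patch) - 1L
        if (nnb <= 1L) next                      # endpoint: preserve
        if (is_simple_point(patch)) {
          sk[p[1], p[2], p[3]] <- FALSE
          removed <- removed + 1L
        }
      }
    }
    if (removed == 0L) break
  }
  # split skeleton into branches
  skel_idx <- which(sk)
  coords <- arrayInd(skel_idx, d)
  degenerate <- FALSE
  offs <- neighbor_offsets(26)
  deg <- integer(length(skel_idx))
  linmap <- array(0L, dim = d); linmap[skel_idx] <- seq_along(skel_idx)
  nbrs <- vector("list", length(skel_idx))
  for (i in seq_along(skel_idx)) {
    nb <- sweep(offs, 2, coords[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nn <- linmap[lin]; nn <- nn[nn > 0L]
    nbrs[[i]] <- nn
    deg[i] <- length(nn)
  }
  junction <- deg > 2L
  segments <- list()
  visited <- logical(length(skel_idx))
  visited[junction] <- TRUE                      # junctions split branches
  for (start in order(-as.integer(deg == 1L))) { # prefer endpoints as starts
    if (visited[start]) next
    # walk in both directions from start through non-junction voxels
    chain <- start; visited[start] <- TRUE
    for (dir in 1:2) {
      cur <- start
      repeat {
        nxt <- nbrs[[cur]]
        nxt <- nxt[!visited[nxt] & !junction[nxt]]
        if (!length(nxt)) break
        cur <- nxt[1]
        visited[cur] <- TRUE
        chain <- if (dir == 1) c(chain, cur) else c(cur, chain)
      }
    }
    segments[[length(segments) + 1L]] <- chain
  }
  if (!length(segments)) {                       # everything was a junction
    segments <- list(which(junction))
    degenerate <- TRUE
  }
  if (length(skel_idx) == 1L) degenerate <- TRUE
  # prune short terminal spurs if anything longer remains
  lens <- vapply(segments, length, 0L)
  if (any(lens >= min_branch)) {
    is_spur <- vapply(segments, function(ch)
      length(ch) < min_branch && any(deg[ch] == 1L), TRUE)
    segments <- segments[!is_spur]
  }
  # corner splitting and mm conversion
  out_segs <- list()
  for (ch in segments) {
    pts <- sweep(coords[ch, , drop = FALSE] - 1, 2, spacing, `*`)
    np <- nrow(pts)
    lag <- 5L
    if (np >= 2 * lag + 1) {
      # Chord directions over a 5-point lag. Thinning rounds a sharp bend
      # into a diagonal staircase spanning roughly the tube radius in
      # voxels (up to ~3 at the working resolution), so short chords never
      # see the full turn; the lag must exceed that half-span.
      ctr_i <- (lag + 1L):(np - lag)
      v1 <- pts[ctr_i, , drop = FALSE] - pts[ctr_i - lag, , drop = FALSE]
      v2 <- pts[ctr_i + lag, , drop = FALSE] - pts[ctr_i, , drop = FALSE]
      cosang <- rowSums(v1 * v2) /
        pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
      bent <- cosang < cos(corner_deg * pi / 180)
      # take one cut per run of bent chords (the sharpest point)
      corners <- integer(0)
      r <- rle(bent)
      pos <- cumsum(r$lengths)
      for (k in seq_along(r$values)) if (r$values[k]) {
        run <- (pos[k] - r$lengths[k] + 1L):pos[k]
        corners <- c(corners, ctr_i[run[which.min(cosang[run])]])
      }
      cuts <- c(0L, corners, np)
      for (s in seq_len(length(cuts) - 1L)) {
        seg <- pts[(cuts[s] + 1L):cuts[s + 1L], , drop = FALSE]
        if (nrow(seg) >= 1) out_segs[[length(out_segs) + 1L]] <- seg
      }
    } else out_segs[[length(out_segs) + 1L]] <- pts
  }
  structure(list(segments = out_segs,
                 ids = sprintf("seg_%02d", seq_along(out_segs)),
                 degenerate = degenerate, spacing = spacing),
            class = "centerline_set")
}

# mm coordinates of background voxel centers 6-adjacent to the mask
mask_boundary_points <- function(mask, spacing) {
  d <- dim(mask)
  shell <- array(FALSE, dim = d)
  for (dd in seq_len(6)) {
    o <- neighbor_offsets(6)[dd, ]
    shifted <- shift3(array(as.logical(mask), d), o[1], o[2], o[3])
    shell <- shell | (!mask & shifted)
  }
  bidx <- which(shell)
  if (!length(bidx)) return(NULL)
  t(sweep(arrayInd(bidx, d) - 1, 2, spacing, `*`))   # 3 x nb
}

# min distance from each row of pts_mm (n x 3) to the boundary set (3 x nb)
boundary_distance <- function(bc, pts_mm) {
  if (is.null(bc)) return(rep(Inf, nrow(pts_mm)))
  apply(pts_mm, 1, function(p) sqrt(min(colSums((bc - p)^2))))
}

#' Per-segment radius from distance-transform samples along the centerline
#'
#' At `min_samples` (default 5) evenly spaced centerline positions —
#' excluding a 10% margin at each end, where the distance transform is
#' biased — the radius sample is the Euclidean distance transform of the
#' mask (distance to the nearest background voxel center) evaluated at the
#' centerline point after local sub-voxel recentering: the skeleton is
#' quantized to voxel centers while the tube axis generally runs between
#' them, so each sample position is moved, within half a voxel, to the
#' point maximizing the distance transform (the local maximal-inscribed-
#' sphere center). The representative radius is the mean of the samples.
#' Segments too short for `min_samples` interior points use all available
#' points and are flagged.
#'
#' @param mask Logical 3D vessel mask.
#' @param cl A `centerline_set` from [extract_centerline()].
#' @param min_samples Minimum samples per segment (default 5).
#' @param spacing Voxel spacing, mm.
#' @return data.frame: segment id, n_samples, radius_mm, flagged; the
#'   per-segment sample vectors are attached as the `samples` attribute.
#' @export
segment_radius <- function(mask, cl, min_samples = 5, spacing = NULL) {
  stopifnot(inherits(cl, "centerline_set"))
  if (is.null(spacing)) spacing <- cl$spacing
  res <- data.frame(segment = character(), n_samples = integer(),
                    radius_mm = numeric(), flagged = logical(),
                    stringsAsFactors = FALSE)
  samples <- list()
  bc <- mask_boundary_points(mask, spacing)
  for (si in seq_along(cl$segments)) {
    pts <- cl$segments[[si]]
    np <- nrow(pts)
    margin <- max(1L, ceiling(0.1 * np))
    interior <- if (np > 2 * margin) (margin + 1L):(np - margin) else seq_len(np)
    flagged <- length(interior) < min_samples
    take <- if (length(interior) <= min_samples) interior
            else interior[round(seq(1, length(interior), length.out = min_samples))]
    sub <- as.matrix(expand.grid(seq(-0.5, 0.5, 0.25), seq(-0.5, 0.5, 0.25),
                                 seq(-0.5, 0.5, 0.25)))
    sub <- sweep(sub, 2, spacing, `*`)
    rad <- vapply(take, function(i) {
      cand <- sweep(sub, 2, pts[i, ], `+`)
      max(boundary_distance(bc, cand))
    }, 0)
    # nearest background voxel *center* lies on average a quarter voxel
    # beyond the mask surface; correct the sample for that offset
    rad <- pmax(rad - mean(spacing) / 4, mean(spacing) / 4)
    samples[[cl$ids[si]]] <- rad
    res <- rbind(res, data.frame(segment = cl$ids[si],
                                 n_samples = length(take),
                                 radius_mm = mean(rad), flagged = flagged,
                                 stringsAsFactors = FALSE))
  }
  attr(res, "samples") <- samples
  res
}

#' Add simulated measurement noise to radius samples (second rater)
#'
#' Emulates an independent operator re-measuring every radius sample;
#' deterministic for a given seed.
#'
#' @param radii Output of [segment_radius()].
#' @param noise_sd Gaussian noise SD in mm.
#' @param seed Integer seed.
#' @return data.frame of the same shape with perturbed samples and means.
#' @export
rater_perturb <- function(radii, noise_sd, seed = 1) {
  samples <- attr(radii, "samples")
  out <- radii
  with_seed(split_seed(seed, 6L), {
    for (i in seq_len(nrow(out))) {
      s <- samples[[out$segment[i]]] + stats::rnorm(length(samples[[out$segment[i]]]),
                                                    sd = noise_sd)
      samples[[out$segment[i]]] <- s
      out$radius_mm[i] <- mean(s)
    }
  })
  attr(out, "samples") <- samples
  out
}

#' Full vessel-radius pipeline on a bright-vessel volume
#'
#' Isotropic interpolation, multiscale Hessian enhancement, region growing,
#' centerline extraction, and distance-based radius averaging.
#'
#' @param vol 3D magnitude volume with `spacing`.
#' @param iso_mm Working isotropic resolution (default 0.86 mm).
#' @param params [vesselness_params()].
#' @param seed_thr,grow_thr Region-growing thresholds (fractions of max).
#' @param min_samples Radius samples per segment (default 5).
#' @return List: `vesselness`, `mask`, `centerlines`, `radii`.
#' @export
vessel_radius_pipeline <- function(vol, iso_mm = 0.86,
                                   params = vesselness_params(),
                                   seed_thr = 0.5, grow_thr = 0.15,
                                   min_samples = 5) {
  sp <- vol_spacing(vol)
  iso <- if (all(abs(sp - iso_mm) < 1e-9)) vol else
    interpolate_isotropic(vol, iso_mm, sp)
  vn <- hessian_vesselness(iso, params)
  mk <- region_grow_vessels(vn, seed_thr, grow_thr, intensity = iso)
  cl <- extract_centerline(mk)
  rr <- segment_radius(mk, cl, min_samples)
  list(vesselness = vn, mask = mk, centerlines = cl, radii = rr)
}
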