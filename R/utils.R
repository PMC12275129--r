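#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation so each synthetic module can be
# regenerated independently from one master seed. Kept below 2^31.
split_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 7919 + counter * 104729) %% 2147483587)
}

#' Run an expression with a locally-scoped RNG seed
#'
#' Saves and restores `.Random.seed` so phantom generation does not disturb
#' the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

stop_if_not_mask <- function(mask, dims) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(mask)), as.integer(dims[1:3])))
    stop("mask shape does not match volume spatial shape", call. = FALSE)
  if (sum(mask != 0) < 1L) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

check_vol4d <- function(vol) {
  if (!is.array(vol) || length(dim(vol)) != 4L)
    stop("expected a 4D array (x, y, z, t)", call. = FALSE)
  if (!all(is.finite(vol))) stop("volume contains non-finite values", call. = FALSE)
  invisible(dim(vol))
}

# Flatten the spatial dims of a 4D array into a time x voxel matrix and back.
vol_to_mat <- function(vol) {
  d <- dim(vol)
  t(matrix(vol, nrow = prod(d[1:3]), ncol = d[4]))
}

mat_to_vol <- function(m, dims) {
  array(t(m), dim = dims)
}

# Offsets for 6/18/26 grid connectivity (memoized; called in hot loops).
.offset_cache <- new.env(parent = emptyenv())
neighbor_offsets <- function(connectivity = 26) {
  key <- as.character(connectivity)
  if (!is.null(.offset_cache[[key]])) return(.offset_cache[[key]])
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(key,
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  out <- unname(as.matrix(g[keep, , drop = FALSE]))
  .offset_cache[[key]] <- out
  out
}
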