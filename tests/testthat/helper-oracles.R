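# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own fast implementations.

# O(N^2) gFCD: full Pearson correlation matrix via stats::cor, count
# partners with r > r_thr, self excluded.
gfcd_brute <- function(vol, mask, r_thr = 0.6) {
  d <- dim(vol)
  Y <- t(matrix(vol, nrow = prod(d[1:3]), ncol = d[4]))   # time x voxel
  idx <- which(mask != 0)
  R <- stats::cor(Y[, idx, drop = FALSE])
  counts <- rowSums(R > r_thr) - 1L
  out <- array(0, dim = d[1:3])
  out[idx] <- counts
  out
}

# Brute lFCD: grow a cluster from each seed; a voxel joins when it is a
# spatial neighbor of the current cluster AND correlates with the SEED
# above r_thr. Value = final cluster size minus the seed.
lfcd_brute <- function(vol, mask, r_thr = 0.6, connectivity = 26) {
  d <- dim(vol)
  dims <- d[1:3]
  Y <- t(matrix(vol, nrow = prod(dims), ncol = d[4]))
  idx <- which(mask != 0)
  R <- stats::cor(Y[, idx, drop = FALSE])
  coords <- arrayInd(idx, dims)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  offs <- as.matrix(g[keep, , drop = FALSE])
  lin_of <- function(p) p[, 1] + (p[, 2] - 1) * dims[1] +
    (p[, 3] - 1) * dims[1] * dims[2]
  pos_of <- match(seq_len(prod(dims)), idx)    # linear voxel -> column of R
  n <- length(idx)
  counts <- integer(n)
  for (s in seq_len(n)) {
    inclust <- logical(n)
    inclust[s] <- TRUE
    front <- s
    while (length(front)) {
      cand <- integer(0)
      for (f in front) {
        p <- sweep(offs, 2, coords[f, ], `+`)
        ok <- p[, 1] >= 1 & p[, 1] <= dims[1] & p[, 2] >= 1 &
          p[, 2] <= dims[2] & p[, 3] >= 1 & p[, 3] <= dims[3]
        cc <- pos_of[lin_of(p[ok, , drop = FALSE])]
        cand <- c(cand, cc[!is.na(cc)])
      }
      cand <- unique(cand)
      cand <- cand[!inclust[cand] & R[s, cand] > r_thr]
      inclust[cand] <- TRUE
      front <- cand
    }
    counts[s] <- sum(inclust) - 1L
  }
  out <- array(0, dim = dims)
  out[idx] <- counts
  out
}

# All permutations of 1..n by simple recursion (n <= 8 in tests).
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Tie-corrected Kruskal-Wallis H computed from first principles.
kw_H_hand <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * (mean(x) - (N + 1) / 2)^2))
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact permutation p for KW by complete enumeration over label orders.
kw_enum_p <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  H_obs <- kw_H_hand(values, groups)
  P <- perms_of(n)
  Hs <- apply(P, 1, function(pm) kw_H_hand(values, groups[pm]))
  mean(Hs >= H_obs - 1e-12)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
wsr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vs <= v_obs), mean(Vs >= v_obs)))
}

# AUC by exhaustive concordant-pair counting (ties count 1/2).
auc_pairs <- function(scores, labels) {
  yf <- factor(labels)
  pos <- scores[as.integer(yf) == 2]
  neg <- scores[as.integer(yf) == 1]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Hand-written Benjamini-Hochberg step-up.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
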