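# ROI-level statistical battery: omnibus nonparametric comparisons with
# linear step-up FDR, protected rank-based post-hoc contrasts, (partial)
# Spearman correlation, inter-rater reliability, and LASSO/ROC biomarker
# selection.

#' Mean map value per atlas label
#'
#' @param m 3D metric map.
#' @param atlas List with `labels` (3D integer array, 0 = background) and
#'   `table` (label/name data.frame), as produced by [make_atlas()].
#' @return data.frame: label, name, mean (NA for empty labels, flagged).
#' @export
roi_means <- function(m, atlas) {
  lab <- atlas$labels
  if (!identical(dim(m), dim(lab))) stop("map and atlas grids differ", call. = FALSE)
  tab <- atlas$table
  means <- vapply(tab$label, function(l) {
    v <- m[lab == l]
    if (!length(v)) NA_real_ else mean(v)
  }, 0)
  data.frame(label = tab$label, name = tab$name, mean = means,
             empty = is.na(means), stringsAsFactors = FALSE)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with p from the chi-square approximation on
#' `k - 1` df (reported as "Chi-square" in group comparisons). For tiny
#' samples an exact permutation p over all group assignments is available.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/vector of group labels, same length.
#' @param exact If `TRUE`, compute the permutation p-value by complete
#'   enumeration (feasible for total n up to ~10).
#' @return List: `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- factor(groups)
  if (length(unique(values)) == 1L)
    stop("all values identical: H undefined after tie correction", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  out <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
              p.value = kt$p.value)
  if (exact) {
    n <- length(values)
    if (n > 10) stop("exact enumeration limited to n <= 10", call. = FALSE)
    H_of <- function(perm) {
      unname(stats::kruskal.test(values, groups[perm])$statistic)
    }
    perms <- gtools_permutations(n)
    H_obs <- out$statistic
    Hs <- apply(perms, 1, H_of)
    out$p.value <- mean(Hs >= H_obs - 1e-12)
    out$exact <- TRUE
  }
  out
}

# all permutations of 1..n (n small); avoids an external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * nrow(sub) + 1):(i * nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Benjamini-Hochberg linear step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} (p_(j) m / j)`, clipped at 1 and mapped back to
#' the input order; never smaller than the raw p.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Protected pairwise post-hoc comparisons after a Kruskal-Wallis omnibus
#'
#' Rank-based least-significant-difference contrasts (Conover-Iman): t
#' statistics on the global ranks with pooled rank variance and `N - k`
#' df, unadjusted. Intended to be run only on omnibus FDR survivors (the
#' caller enforces the protected design). `method = "raw_t"` gives the
#' literal LSD on raw values instead.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (k = 3 typical).
#' @param method `"ranks"` (default) or `"raw_t"`.
#' @return data.frame: group1, group2, statistic, p.value, direction
#'   (sign of the first group's median minus the second's).
#' @export
lsd_posthoc <- function(values, groups, method = c("ranks", "raw_t")) {
  method <- match.arg(method)
  groups <- factor(groups)
  k <- nlevels(groups)
  N <- length(values)
  lv <- levels(groups)
  y <- if (method == "ranks") rank(values) else values
  gm <- tapply(y, groups, mean)
  ns <- tapply(y, groups, length)
  if (method == "ranks") {
    H <- unname(stats::kruskal.test(values, groups)$statistic)
    S2 <- stats::var(y)
    pooled <- S2 * (N - 1 - H) / (N - k)
  } else {
    ssw <- sum(tapply(y, groups, function(v) sum((v - mean(v))^2)))
    pooled <- ssw / (N - k)
  }
  res <- NULL
  meds <- tapply(values, groups, stats::median)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(pooled * (1 / ns[i] + 1 / ns[j]))
    tstat <- (gm[i] - gm[j]) / se
    p <- 2 * stats::pt(-abs(tstat), df = N - k)
    res <- rbind(res, data.frame(group1 = lv[i], group2 = lv[j],
                                 statistic = unname(tstat), p.value = unname(p),
                                 direction = sign(meds[i] - meds[j]),
                                 stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation on (average-tie) ranks;
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors.
#' @return List: `rho`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance after ranking", call. = FALSE)
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
  list(rho = rho, p.value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Partial Spearman correlation controlling for covariates
#'
#' All variables are rank-transformed; x and y ranks are residualized on
#' the covariate ranks (OLS with intercept) and the Pearson correlation of
#' the residuals is tested on `n - 2 - k` df.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data.frame of covariates (factors must
#'   be pre-coded numerically).
#' @return List: `rho`, `p.value`, `n`, `n_covariates`.
#' @export
partial_spearman <- function(x, y, covariates) {
  Z <- as.matrix(covariates)
  ok <- is.finite(x) & is.finite(y) & apply(Z, 1, function(r) all(is.finite(r)))
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x); k <- ncol(Z)
  if (n < 4 + k) stop("need n >= 4 + number of covariates", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  RZ <- apply(Z, 2, rank)
  fit <- function(v) stats::lm.fit(cbind(1, RZ), v)$residuals
  ex <- fit(rx); ey <- fit(ry)
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0)
    stop("zero residual variance", call. = FALSE)
  rho <- stats::cor(ex, ey)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, 1e-15))
  list(rho = rho, p.value = 2 * stats::pt(-abs(tstat), df = df), n = n,
       n_covariates = k)
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measurement
#'
#' From the two-way ANOVA decomposition:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param ratings n x k numeric matrix (subjects x raters; k = 2 typical).
#' @return List: `icc`, `ms` (mean squares).
#' @export
icc_two_way_random <- function(ratings) {
  X <- as.matrix(ratings)
  n <- nrow(X); k <- ncol(X)
  if (n < 3 || k < 2) stop("need >= 3 subjects and >= 2 raters", call. = FALSE)
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((X - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR < 1e-300) stop("zero between-subject variance", call. = FALSE)
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  list(icc = icc, ms = c(MSR = MSR, MSC = MSC, MSE = MSE))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Exact p for up to 25 non-zero differences without ties, normal
#' approximation with tie correction otherwise. All-zero differences yield
#' the degenerate p = 1 with a flag.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `statistic` (V), `p.value`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d[d != 0]
  if (!length(nz)) return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  if (length(nz) < 5)
    warning("fewer than 5 non-zero differences; test has little power")
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       degenerate = FALSE)
}

#' LASSO-penalized logistic regression with stratified 10-fold CV
#'
#' Coordinate-descent L1 path (via glmnet) over a log-spaced grid; the CV
#' loss is the mean squared error between predicted probability and the
#' 0/1 label. By default the penalty follows the one-standard-error rule
#' (largest penalty whose CV loss is within one standard error of the
#' minimum), the standard conservative choice when the goal is sparse
#' variable selection; `rule = "min"` uses the minimizer. The model is refit on
#' all data at that penalty; selected predictors are those with nonzero
#' coefficients. Predictors are standardized internally.
#'
#' @param X Numeric predictor matrix / data.frame.
#' @param y Binary outcome (2 levels).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the stratified fold assignment.
#' @param loss `"mse"` (default, Brier-type) or `"deviance"`.
#' @param rule Lambda selection rule: `"1se"` (default; one-standard-error
#'   rule, the standard conservative choice for sparse variable selection)
#'   or `"min"` (CV-loss minimizer).
#' @return List of class `lasso_result`: `selected`, `coefficients`
#'   (including zeros), `lambda`, `cv_loss` (per-lambda mean CV loss),
#'   `foldid`, `fit` (the cv.glmnet object).
#' @export
lasso_logistic_cv <- function(X, y, folds = 10, seed = 1,
                              loss = c("mse", "deviance"),
                              rule = c("1se", "min")) {
  loss <- match.arg(loss)
  rule <- match.arg(rule)
  X <- as.matrix(X)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("outcome must have exactly 2 classes", call. = FALSE)
  yb <- as.integer(yf) - 1L
  foldid <- integer(length(yb))
  with_seed(split_seed(seed, 7L), {
    for (cls in 0:1) {
      idx <- which(yb == cls)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  cv <- glmnet::cv.glmnet(X, yb, family = "binomial",
                          type.measure = loss, foldid = foldid,
                          standardize = TRUE)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  co <- as.matrix(stats::coef(cv, s = lam))
  sel <- rownames(co)[-1][co[-1, 1] != 0]
  structure(list(selected = sel, coefficients = co[, 1],
                 lambda = lam, rule = rule, cv_loss = cv$cvm,
                 foldid = foldid, fit = cv),
            class = "lasso_result")
}

#' Area under the ROC curve with a stratified bootstrap CI
#'
#' AUC by the Mann-Whitney identity (tied score pairs count 1/2);
#' percentile bootstrap CI resampling cases and controls separately.
#'
#' @param scores Numeric classifier scores (higher = positive class).
#' @param labels Binary labels.
#' @param ci_boot Bootstrap resamples for the CI (default 2000; 0 skips it).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List: `auc`, `ci` (length 2 or NULL), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, ci_boot = 2000, seed = 1, conf = 0.95) {
  yf <- factor(labels)
  if (nlevels(yf) != 2) stop("both classes must be present", call. = FALSE)
  pos <- scores[as.integer(yf) == 2]
  neg <- scores[as.integer(yf) == 1]
  auc_of <- function(p, q) {
    r <- rank(c(p, q))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(q))
  }
  auc <- auc_of(pos, neg)
  ci <- NULL
  if (ci_boot > 0) {
    bs <- with_seed(split_seed(seed, 8L), {
      vapply(seq_len(ci_boot), function(i)
        auc_of(sample(pos, replace = TRUE), sample(neg, replace = TRUE)), 0)
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a)))
  }
  list(auc = auc, ci = ci, n_pos = length(pos), n_neg = length(neg))
}

#' Run the full omnibus + correlation testing plan on a cohort table
#'
#' Orchestrates the family structure of the analysis: Kruskal-Wallis per
#' ROI with FDR pooled *within metric* across all that metric's ROI columns
#' (both atlases together); protected post-hoc contrasts only on FDR
#' survivors; Spearman correlations with FDR pooled within
#' (metric, group, atlas) across the cognitive battery.
#'
#' @param cohort data.frame from [make_cohort()] (or same layout).
#' @param plan List with elements: `kw` — named list, metric name ->
#'   character vector of ROI column names; `alpha` (default 0.05);
#'   `posthoc` (`"ranks"`/`"raw_t"`); optionally `correlations` — list of
#'   `list(column, metric, group, atlas)` entries tested against all
#'   `plan$scores` (default [cognitive_tests()]); optionally
#'   `partial_covariates` — column names controlled for in a parallel
#'   partial-correlation pass.
#' @return List: `omnibus` (long data.frame with H, df, p, p_fdr and
#'   post-hoc columns) and `correlations` (rho, p, p_fdr and, when
#'   requested, partial rho/p).
#' @export
fdr_scope_runner <- function(cohort, plan) {
  alpha <- if (is.null(plan$alpha)) 0.05 else plan$alpha
  posthoc <- if (is.null(plan$posthoc)) "ranks" else plan$posthoc
  scores <- if (is.null(plan$scores)) cognitive_tests() else plan$scores
  omnibus <- NULL
  for (metric in names(plan$kw)) {
    cols <- plan$kw[[metric]]
    miss <- setdiff(cols, names(cohort))
    if (length(miss)) stop("unknown ROI column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    rows <- lapply(cols, function(cl) {
      kw <- kruskal_wallis(cohort[[cl]], cohort$group)
      data.frame(metric = metric, roi = cl, statistic = kw$statistic,
                 df = kw$df, p = kw$p.value, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$p_fdr <- fdr_bh(fam$p)
    omnibus <- rbind(omnibus, fam)
  }
  if (!is.null(omnibus)) {
    omnibus$significant <- omnibus$p_fdr < alpha
    ph_cols <- c("p_hc_pdnc", "p_hc_pdmci", "p_pdnc_pdmci",
                 "dir_hc_pdnc", "dir_hc_pdmci", "dir_pdnc_pdmci")
    for (cc in ph_cols) omnibus[[cc]] <- NA_real_
    for (i in which(omnibus$significant)) {
      ph <- lsd_posthoc(cohort[[omnibus$roi[i]]], cohort$group, method = posthoc)
      omnibus[i, c("p_hc_pdnc", "p_hc_pdmci", "p_pdnc_pdmci")] <- ph$p.value
      omnibus[i, c("dir_hc_pdnc", "dir_hc_pdmci", "dir_pdnc_pdmci")] <- ph$direction
    }
  }
  corr <- NULL
  if (!is.null(plan$correlations)) {
    fam_key <- vapply(plan$correlations, function(e)
      paste(e$metric, e$group, e$atlas, sep = "|"), "")
    for (key in unique(fam_key)) {
      entries <- plan$correlations[fam_key == key]
      fam <- NULL
      for (e in entries) {
        sub <- cohort[cohort$group == e$group, ]
        for (sc in scores) {
          ct <- spearman_cor(sub[[e$column]], sub[[sc]])
          row <- data.frame(metric = e$metric, group = e$group,
                            atlas = e$atlas, roi = e$column, score = sc,
                            rho = ct$rho, p = ct$p.value,
                            stringsAsFactors = FALSE)
          if (!is.null(plan$partial_covariates)) {
            Z <- sub[plan$partial_covariates]
            Z[] <- lapply(Z, function(v) if (is.numeric(v)) v
                          else as.integer(factor(v)))
            pc <- partial_spearman(sub[[e$column]], sub[[sc]], Z)
            row$partial_rho <- pc$rho; row$partial_p <- pc$p.value
          }
          fam <- rbind(fam, row)
        }
      }
      fam$p_fdr <- fdr_bh(fam$p)
      corr <- rbind(corr, fam)
    }
    if (!is.null(corr)) corr$significant <- corr$p_fdr < alpha
  }
  list(omnibus = omnibus, correlations = corr)
}
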