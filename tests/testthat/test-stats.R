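test_that("kruskal_wallis reproduces stats::kruskal.test and enumerates exactly", {
  set.seed(1)
  v <- rnorm(30); g <- factor(rep(1:3, each = 10))
  got <- kruskal_wallis(v, g)
  ref <- stats::kruskal.test(v, g)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p.value, ref$p.value)
  # exact enumeration matches the independent oracle at n = 7
  set.seed(2)
  v2 <- rnorm(7); g2 <- factor(c(1, 1, 2, 2, 3, 3, 3))
  expect_equal(kruskal_wallis(v2, g2, exact = TRUE)$p.value,
               kw_enum_p(v2, g2), tolerance = 1e-12)
  expect_error(kruskal_wallis(rep(1, 9), factor(rep(1:3, 3))), "identical")
  expect_error(kruskal_wallis(rnorm(12), factor(rep(1:3, 4)), exact = TRUE),
               "n <= 10")
})

test_that("fdr_bh matches p.adjust and an independent step-up", {
  set.seed(3)
  p <- runif(25)
  expect_equal(fdr_bh(p), p.adjust(p, "BH"))
  expect_equal(fdr_bh(p), bh_hand(p))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_true(all(fdr_bh(p) >= p))
  expect_true(all(fdr_bh(p) <= 1))
})

test_that("lsd_posthoc separates shifted groups with signed direction", {
  set.seed(4)
  v <- c(rnorm(15, 3), rnorm(15, 0), rnorm(15, -3))
  g <- factor(rep(c("HC", "PD-NC", "PD-MCI"), each = 15),
              levels = c("HC", "PD-NC", "PD-MCI"))
  ph <- lsd_posthoc(v, g)
  expect_identical(nrow(ph), 3L)
  expect_true(all(ph$p.value < 0.001))
  expect_true(all(ph$direction == 1))       # first-listed group higher
  ph2 <- lsd_posthoc(-v, g)
  expect_true(all(ph2$direction == -1))
  # raw_t variant runs on the same interface
  pht <- lsd_posthoc(v, g, method = "raw_t")
  expect_true(all(pht$p.value < 0.001))
  # null data: p-values are not all significant
  set.seed(5)
  phn <- lsd_posthoc(rnorm(45), g)
  expect_true(any(phn$p.value > 0.05))
})

test_that("spearman_cor matches cor.test's t-approximation", {
  set.seed(6)
  x <- rnorm(40); y <- x + rnorm(40)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(cor(rank(x), rank(y)), got$rho)
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("partial_spearman removes a common driver and keeps direct links", {
  set.seed(7)
  n <- 200
  z <- rnorm(n)
  x <- z + rnorm(n, sd = 0.3)
  y <- z + rnorm(n, sd = 0.3)
  plain <- spearman_cor(x, y)
  part <- partial_spearman(x, y, cbind(z))
  expect_gt(plain$rho, 0.8)
  expect_lt(abs(part$rho), 0.15)
  # a direct association survives partialling an irrelevant covariate
  y2 <- x + rnorm(n, sd = 0.3)
  part2 <- partial_spearman(x, y2, cbind(rnorm(n)))
  expect_gt(part2$rho, 0.8)
  expect_identical(part2$n_covariates, 1L)
})

test_that("ICC(2,1) hits its closed-form anchors", {
  set.seed(8)
  m <- rnorm(25)
  expect_equal(icc_two_way_random(cbind(m, m))$icc, 1)
  # duplicate with a pure rater offset of 1: the absolute-agreement
  # denominator gains k*MSC/n = 1, so ICC = MSR / (MSR + 1) exactly
  off <- icc_two_way_random(cbind(m, m + 1))$icc
  MSR <- 2 * var(m)
  expect_equal(off, MSR / (MSR + 1), tolerance = 1e-8)
  expect_lt(off, 1)
  expect_error(icc_two_way_random(cbind(rep(1, 10), rep(1, 10))), "variance")
  expect_error(icc_two_way_random(matrix(1:4, 2, 2)), ">= 3")
})

test_that("wilcoxon_signed_rank matches enumeration and flags degeneracy", {
  set.seed(9)
  x <- rnorm(8); y <- x + rnorm(8)
  got <- wilcoxon_signed_rank(x, y)
  expect_equal(got$p.value, wsr_enum_p(x - y), tolerance = 1e-12)
  deg <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)
})

test_that("roc_auc equals exhaustive pair counting and hits anchors", {
  sc <- c(1, 2, 3, 4); lb <- factor(c("a", "b", "a", "b"))
  expect_equal(roc_auc(sc, lb, ci_boot = 0)$auc, 0.75)
  expect_equal(roc_auc(sc, lb, ci_boot = 0)$auc, auc_pairs(sc, lb))
  # perfect separation and chance
  expect_equal(roc_auc(c(1, 2, 8, 9), factor(c(0, 0, 1, 1)),
                       ci_boot = 0)$auc, 1)
  set.seed(10)
  sc2 <- rnorm(60); lb2 <- factor(rep(0:1, 30))
  expect_equal(roc_auc(sc2, lb2, ci_boot = 0)$auc, auc_pairs(sc2, lb2))
  # bootstrap CI brackets the point estimate and is deterministic in seed
  r1 <- roc_auc(sc2, lb2, ci_boot = 200, seed = 4)
  r2 <- roc_auc(sc2, lb2, ci_boot = 200, seed = 4)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$auc && r1$auc <= r1$ci[2])
})

test_that("lasso_logistic_cv selects a strong predictor and is seed-stable", {
  set.seed(11)
  y <- factor(rep(c("a", "b"), each = 30))
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 2] <- X[, 2] + ifelse(y == "b", 2, 0)
  f1 <- lasso_logistic_cv(X, y, seed = 3)
  expect_true("v2" %in% f1$selected)
  expect_identical(f1$selected, lasso_logistic_cv(X, y, seed = 3)$selected)
  expect_identical(f1$rule, "1se")
  # folds are stratified: both classes in every fold
  tab <- table(f1$foldid, y)
  expect_true(all(tab > 0))
  expect_error(lasso_logistic_cv(X, rep("a", 60)), "2 classes")
})

test_that("roi_means averages per label and flags empty ROIs", {
  at <- make_atlas(c(6, 6, 4), n_labels = 3, seed = 1)
  m <- array(0, dim = c(6, 6, 4))
  for (l in 1:3) m[at$labels == l] <- l * 10
  rm_ <- roi_means(m, at)
  expect_equal(rm_$mean, c(10, 20, 30))
  expect_false(any(rm_$empty))
  # an absent label yields NA + empty flag
  at2 <- at; at2$table <- rbind(at2$table, data.frame(label = 9, name = "gone"))
  rm2 <- roi_means(m, at2)
  expect_true(rm2$empty[4])
})

test_that("fdr_scope_runner pools FDR within metric and protects post-hocs", {
  co <- make_cohort(cohort_spec(
    metrics = c("a_r1", "a_r2", "b_r1", "b_r2"),
    effects = list(a_r1 = c(0, -1, -2)), seed = 12))
  st <- fdr_scope_runner(co, list(kw = list(a = c("a_r1", "a_r2"),
                                            b = c("b_r1", "b_r2"))))
  om <- st$omnibus
  expect_identical(nrow(om), 4L)
  # within-metric pooling: each family's adjusted values equal fdr_bh of
  # that family's raw p's alone
  for (mt in c("a", "b")) {
    fam <- om[om$metric == mt, ]
    expect_equal(fam$p_fdr, fdr_bh(fam$p))
  }
  # post-hoc columns filled only for survivors
  expect_true(om$significant[om$roi == "a_r1"])
  expect_false(is.na(om$p_hc_pdmci[om$roi == "a_r1"]))
  expect_true(all(is.na(om$p_hc_pdmci[!om$significant])))
  expect_identical(om$dir_hc_pdmci[om$roi == "a_r1"], 1)
  expect_error(fdr_scope_runner(co, list(kw = list(a = "missing_col"))),
               "unknown ROI")
})

test_that("fdr_scope_runner correlation families span the cognitive battery", {
  co <- make_cohort(cohort_spec(
    metrics = "m1",
    target_rho = list(metric = "m1", score = "MMSE", group = "PD-MCI",
                      rho = 0.9), seed = 13))
  plan <- list(kw = list(m = "m1"),
               correlations = list(
                 list(column = "m1", metric = "m1", group = "PD-MCI",
                      atlas = "aal")),
               partial_covariates = c("age", "sex", "education"))
  st <- fdr_scope_runner(co, plan)
  cr <- st$correlations
  expect_identical(nrow(cr), length(cognitive_tests()))
  expect_equal(cr$p_fdr, fdr_bh(cr$p))
  expect_true(all(c("partial_rho", "partial_p") %in% names(cr)))
  # the planted correlation is the family's strongest and survives FDR
  expect_identical(cr$score[which.max(abs(cr$rho))], "MMSE")
  expect_true(cr$significant[cr$score == "MMSE"])
})
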