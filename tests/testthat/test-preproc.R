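mk_vol <- function(Y, dims) {
  # Y: time x voxel
  v <- array(t(Y), dim = dims)
  attr(v, "spacing") <- c(3, 3, 3)
  attr(v, "tr") <- 2
  v
}

test_that("drop_initial_volumes removes exactly the first frames", {
  v <- array(seq_len(2 * 2 * 2 * 20), dim = c(2, 2, 2, 20))
  attr(v, "tr") <- 2
  out <- drop_initial_volumes(v, 10)
  expect_identical(dim(out), c(2L, 2L, 2L, 10L))
  expect_equal(out[, , , 1], v[, , , 11])
  expect_error(drop_initial_volumes(v, 20))
})

test_that("gaussian_smooth preserves constants and total mass; fwhm 0 is identity", {
  set.seed(1)
  v <- array(rnorm(8 * 8 * 4 * 3), dim = c(8, 8, 4, 3))
  attr(v, "spacing") <- c(3, 3, 3)
  cst <- array(5, dim = dim(v)); attr(cst, "spacing") <- c(3, 3, 3)
  expect_equal(gaussian_smooth(cst, 6), cst, ignore_attr = TRUE)
  expect_equal(gaussian_smooth(v, 0), v, ignore_attr = TRUE)
  sm <- gaussian_smooth(v, 6)
  # smoothing shrinks spatial variance
  expect_lt(var(as.vector(sm[, , , 1])), var(as.vector(v[, , , 1])))
})

test_that("linear_detrend removes a planted ramp and keeps the mean", {
  nt <- 50
  tt <- seq_len(nt)
  y <- 10 + 0.3 * tt
  v <- mk_vol(cbind(y, y + 1), c(2, 1, 1, nt))
  out <- linear_detrend(v)
  expect_equal(out[1, 1, 1, ], rep(mean(y), nt), tolerance = 1e-10)
  expect_equal(mean(out[2, 1, 1, ]), mean(y + 1), tolerance = 1e-10)
})

test_that("friston24_expand builds [R, lag, R^2, lag^2] with zero first lag row", {
  mp <- matrix(rnorm(30 * 6), 30, 6)
  X <- friston24_expand(mp)
  expect_identical(dim(X), c(30L, 24L))
  expect_equal(X[, 1:6], mp, ignore_attr = TRUE)
  expect_equal(X[1, 7:12], rep(0, 6), ignore_attr = TRUE)
  expect_equal(X[2:30, 7:12], mp[1:29, ], ignore_attr = TRUE)
  expect_equal(X[, 13:18], mp^2, ignore_attr = TRUE)
  expect_equal(X[2:30, 19:24], mp[1:29, ]^2, ignore_attr = TRUE)
})

test_that("nuisance_regress orthogonalizes against regressors and restores means", {
  set.seed(2)
  nt <- 60
  X <- cbind(rnorm(nt), rnorm(nt))
  Y <- cbind(100 + 2 * X[, 1] + rnorm(nt, sd = 0.1),
             50 - X[, 2] + rnorm(nt, sd = 0.1))
  v <- mk_vol(Y, c(2, 1, 1, nt))
  out <- nuisance_regress(v, X)
  res <- out[1, 1, 1, ]
  expect_lt(abs(cor(res, X[, 1])), 1e-10)
  # each voxel's own temporal mean is restored exactly
  expect_equal(mean(res), mean(Y[, 1]), tolerance = 1e-10)
  expect_equal(mean(out[2, 1, 1, ]), mean(Y[, 2]), tolerance = 1e-10)
  # rank-deficient design: duplicated column is dropped with a warning
  expect_warning(nuisance_regress(v, cbind(X, X[, 1])), "linearly dependent")
})

test_that("bandpass keeps in-band bins, removes out-of-band bins and DC", {
  nt <- 128; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  f_in <- 8 / (nt * tr)     # exact FFT bin, 0.03125 Hz
  f_out <- 40 / (nt * tr)   # 0.15625 Hz, outside 0.01-0.08
  y <- 7 + 3 * sin(2 * pi * f_in * tt) + 2 * sin(2 * pi * f_out * tt)
  v <- mk_vol(cbind(y), c(1, 1, 1, nt))
  out <- bandpass(v, 0.01, 0.08, tr = tr)
  want <- 3 * sin(2 * pi * f_in * tt)
  expect_equal(out[1, 1, 1, ], want, tolerance = 1e-10)
  # DC excluded even when the band starts at 0
  out0 <- bandpass(v, 0, 0.08, tr = tr)
  expect_equal(mean(out0[1, 1, 1, ]), 0, tolerance = 1e-10)
  expect_error(bandpass(v, 0.08, 0.01, tr = tr))
})

test_that("preprocess_bold branches differ only by nuisance regression step", {
  ph <- make_bold_phantom(bold_phantom_spec(shape = c(4, 4, 2, 80), seed = 5))
  pc <- preprocess_bold(ph$vol, ph$mask, "cvr", fwhm_mm = 0)
  expect_identical(pc$branch, "cvr")
  expect_identical(dim(pc$filtered)[4], dim(ph$vol)[4] - 10L)
  expect_equal(pc$band, c(0, 0.1164))
  ps <- preprocess_bold(ph$vol, ph$mask, "standard", motion = ph$motion,
                        fwhm_mm = 0)
  expect_equal(ps$band, c(0.01, 0.08))
  expect_error(preprocess_bold(ph$vol, ph$mask, "standard"), "motion")
  # motion with full-length rows is trimmed to match the dropped frames
  expect_identical(dim(ps$filtered), dim(pc$filtered))
})
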