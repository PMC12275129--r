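tube <- function(cyls, shape = c(40, 40, 44), noise_sd = 0, seed = 1) {
  make_vessel_phantom(vessel_phantom_spec(shape = shape, cylinders = cyls,
                                          background = 10,
                                          noise_sd = noise_sd, seed = seed))
}

test_that("interpolate_isotropic reproduces linear fields exactly", {
  d <- c(12, 10, 8); sp <- c(0.6, 0.9, 1.2)
  gx <- outer(outer((seq_len(d[1]) - 1) * sp[1], rep(1, d[2])), rep(1, d[3]))
  gy <- aperm(outer(outer((seq_len(d[2]) - 1) * sp[2], rep(1, d[1])),
                    rep(1, d[3])), c(2, 1, 3))
  v <- 2 + 3 * gx - gy
  out <- interpolate_isotropic(v, 0.86, spacing = sp)
  od <- dim(out)
  ex <- 2 + 3 * outer(outer((seq_len(od[1]) - 1) * 0.86, rep(1, od[2])),
                      rep(1, od[3])) -
    aperm(outer(outer((seq_len(od[2]) - 1) * 0.86, rep(1, od[1])),
                rep(1, od[3])), c(2, 1, 3))
  expect_equal(out, ex, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(attr(out, "spacing")), rep(0.86, 3))
})

test_that("sym3_eigenvalues agrees with base::eigen on random matrices", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rnorm(9), 3); m <- (m + t(m)) / 2
    got <- sort(as.vector(neurohemo:::sym3_eigenvalues(
      m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])))
    expect_equal(got, sort(eigen(m, symmetric = TRUE)$values),
                 tolerance = 1e-10)
  }
  # degenerate isotropic case
  expect_equal(as.vector(neurohemo:::sym3_eigenvalues(2, 2, 2, 0, 0, 0)),
               rep(2, 3))
})

test_that("vesselness enhances tubes and suppresses blobs", {
  ph <- tube(list(list(start = c(14, 14, 3), end = c(14, 14, 33),
                       radius = 1.7, intensity = 100)))
  vn <- hessian_vesselness(ph$vol)
  expect_true(all(vn >= 0 & vn <= 1))
  axis_v <- vn[17, 17, 22]                  # on the tube axis
  # sphere of the same radius scale
  d <- c(31, 31, 31)
  sp <- rep(0.86, 3)
  ctr <- (d - 1) / 2 * sp
  gx <- outer(outer((seq_len(d[1]) - 1) * sp[1], rep(1, d[2])), rep(1, d[3]))
  gy <- aperm(gx, c(2, 1, 3))[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  gz <- aperm(gx, c(3, 2, 1))[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  rr <- sqrt((gx - ctr[1])^2 + (gy - ctr[2])^2 + (gz - ctr[3])^2)
  sph <- 10 + 90 * (rr <= 2.5)
  attr(sph, "spacing") <- sp
  vs <- hessian_vesselness(sph)
  sphere_v <- vs[16, 16, 16]
  expect_gt(axis_v, 0.5)
  expect_lt(sphere_v, axis_v / 3)
})

test_that("region growing separates disjoint vessels and fills the lumen", {
  ph <- tube(list(
    list(start = c(8, 8, 3), end = c(8, 8, 33), radius = 1.7,
         intensity = 100),
    list(start = c(24, 24, 3), end = c(24, 24, 33), radius = 1.7,
         intensity = 100)))
  vn <- hessian_vesselness(ph$vol)
  mk <- region_grow_vessels(vn, intensity = ph$vol)
  lab <- neurohemo:::label_components(mk, 26)
  expect_identical(max(lab), 2L)
  expect_true(sum(mk) > 0)
  # an empty map warns and returns an empty mask
  z <- array(0, dim = c(8, 8, 8)); attr(z, "spacing") <- rep(0.86, 3)
  expect_warning(mk0 <- region_grow_vessels(z), "empty")
  expect_false(any(mk0))
  expect_error(region_grow_vessels(vn, seed_thr = 0.2, grow_thr = 0.5))
})

test_that("centerline of a straight tube is a single ordered branch", {
  ph <- tube(list(list(start = c(14, 14, 3), end = c(14, 14, 33),
                       radius = 1.7, intensity = 100)))
  vp <- vessel_radius_pipeline(ph$vol)
  expect_identical(length(vp$centerlines$segments), 1L)
  seg <- vp$centerlines$segments[[1]]
  # ordered: consecutive points are close; monotone along z
  steps <- sqrt(rowSums(diff(seg)^2))
  expect_true(all(steps < 2 * 0.86 + 1e-9))
  expect_true(all(diff(seg[, 3]) > 0) || all(diff(seg[, 3]) < 0))
  # skeleton stays inside the mask and near the true axis (x = y = 14 mm)
  expect_true(all(abs(seg[, 1] - 14) < 0.87))
})

test_that("an L-shaped vessel splits into two branches at the corner", {
  ph <- tube(list(
    list(start = c(4, 16, 16), end = c(28, 16, 16), radius = 1.7,
         intensity = 100),
    list(start = c(28, 16, 16), end = c(28, 16, 30), radius = 1.7,
         intensity = 100)), shape = c(40, 40, 40))
  vp <- vessel_radius_pipeline(ph$vol)
  expect_identical(nrow(vp$radii), 2L)
  expect_equal(vp$radii$radius_mm, rep(1.7, 2), tolerance = 0.15)
})

test_that("radius recovery: single tube within 10%, rising with truth", {
  est <- sapply(c(1.3, 2.4), function(r) {
    ph <- tube(list(list(start = c(14, 14, 2), end = c(14, 14, 34),
                         radius = r, intensity = 100)))
    rr <- vessel_radius_pipeline(ph$vol)$radii
    rr$radius_mm[which.max(rr$n_samples)]
  })
  expect_lt(abs(est[1] - 1.3) / 1.3, 0.10)
  expect_lt(abs(est[2] - 2.4) / 2.4, 0.20)
  expect_gt(est[2], est[1])
})

test_that("segment_radius flags segments with too few samples", {
  ph <- tube(list(list(start = c(14, 14, 14), end = c(14, 14, 20),
                       radius = 1.7, intensity = 100)),
             shape = c(34, 34, 34))
  vp <- vessel_radius_pipeline(ph$vol, min_samples = 25)
  expect_true(all(vp$radii$flagged))
})

test_that("thinning preserves topology: one component in, one skeleton out", {
  ph <- tube(list(list(start = c(6, 6, 4), end = c(26, 26, 30),
                       radius = 1.5, intensity = 100)))
  vp <- vessel_radius_pipeline(ph$vol)
  sk <- array(FALSE, dim = dim(vp$mask))
  for (seg in vp$centerlines$segments) {
    vox <- round(sweep(seg, 2, 0.86, `/`)) + 1
    sk[vox] <- TRUE
  }
  expect_true(all(vp$mask[sk]))              # skeleton lies inside the mask
  lab <- neurohemo:::label_components(vp$mask, 26)
  expect_identical(max(lab), 1L)
})

test_that("rater_perturb reproduces a controlled reliability experiment", {
  ph <- tube(list(list(start = c(14, 14, 3), end = c(14, 14, 33),
                       radius = 1.7, intensity = 100)))
  rr <- vessel_radius_pipeline(ph$vol)$radii
  r2 <- rater_perturb(rr, noise_sd = 0.05, seed = 1)
  expect_identical(r2, rater_perturb(rr, noise_sd = 0.05, seed = 1))
  expect_false(identical(r2$radius_mm, rr$radius_mm))
  r0 <- rater_perturb(rr, noise_sd = 0, seed = 1)
  expect_equal(r0$radius_mm, rr$radius_mm)
})
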