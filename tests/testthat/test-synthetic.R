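test_that("bandlimited_signal has unit variance and pure in-band support", {
  nt <- 128; tr <- 2
  g <- neurohemo:::bandlimited_signal(nt, tr, 0, 0.1164)
  expect_equal(stats::sd(g), 1, tolerance = 1e-10)
  expect_equal(mean(g), 0, tolerance = 1e-10)
  sp <- Mod(stats::fft(g))^2
  f <- neurohemo:::fft_freqs(nt, tr)
  expect_lt(sum(sp[f > 0.1164 + 1e-12]) / sum(sp), 1e-20)
})

test_that("phantom generators are bitwise deterministic in their seed", {
  s <- bold_phantom_spec(shape = c(4, 4, 2, 70), seed = 11)
  expect_identical(make_bold_phantom(s), make_bold_phantom(s))
  a <- asl_phantom_spec(noise_sd = 2, seed = 3)
  expect_identical(make_asl_phantom(a), make_asl_phantom(a))
  vs <- vessel_phantom_spec(cylinders = list(
    list(start = c(5, 14, 5), end = c(25, 14, 28), radius = 1.5,
         intensity = 80)), noise_sd = 2, seed = 7)
  expect_identical(make_vessel_phantom(vs), make_vessel_phantom(vs))
  cs <- cohort_spec(seed = 42)
  expect_identical(make_cohort(cs), make_cohort(cs))
  # and different seeds give different data
  expect_false(identical(make_cohort(cohort_spec(seed = 1)),
                         make_cohort(cohort_spec(seed = 2))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_bold_phantom(bold_phantom_spec(shape = c(4, 4, 2, 70))))
  invisible(make_cohort(cohort_spec()))
  expect_identical(.Random.seed, before)
})

test_that("spec validation rejects malformed phantom requests", {
  expect_error(bold_phantom_spec(shape = c(4, 4, 2, 32)), "nt")
  expect_error(bold_phantom_spec(shape = c(1, 4, 2, 70)), "spatial")
  cl <- as.matrix(expand.grid(1:2, 1:2, 1))
  expect_error(bold_phantom_spec(clusters = list(cl, cl)), "disjoint")
  expect_error(asl_phantom_spec(cbf = -5), "non-negative")
  expect_error(asl_phantom_spec(m0 = 0), "positive")
  expect_error(vessel_phantom_spec(cylinders = list(
    list(start = c(1, 1, 1), end = c(5, 5, 5), radius = 0.3,
         intensity = 1))), "radius")
  expect_error(vessel_phantom_spec(cylinders = list(
    list(start = c(1, 1, 1), end = c(500, 5, 5), radius = 1.5,
         intensity = 1))), "within the grid")
  expect_error(cohort_spec(n_hc = 2), ">= 3")
  expect_error(cohort_spec(target_rho = list(metric = "m", score = "MMSE",
                                             group = "HC", rho = 1.2)))
})

test_that("the BOLD phantom realizes its stated generative model", {
  gain <- array(1, dim = c(4, 4, 2)); gain[1, 1, 1] <- 2
  ph <- make_bold_phantom(bold_phantom_spec(shape = c(4, 4, 2, 96),
                                            gain = gain, noise_sd = 0,
                                            seed = 2))
  G <- ph$truth$global_signal
  expect_equal(ph$vol[1, 1, 1, ], 100 + 2 * G, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(ph$vol[2, 1, 1, ], 100 + G, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(dim(ph$motion), c(96L, 6L))
  expect_true(all(is.finite(ph$motion)))
  expect_equal(vol_tr(ph$vol), 2)
})

test_that("the vessel phantom marks partial-volume occupancy correctly", {
  sp <- vessel_phantom_spec(shape = c(24, 24, 24), cylinders = list(
    list(start = c(2, 10, 10), end = c(18, 10, 10), radius = 1.6,
         intensity = 100)), background = 10, noise_sd = 0)
  ph <- make_vessel_phantom(sp)
  # axis voxels are fully inside -> full intensity
  expect_equal(max(ph$vol), 100, tolerance = 1e-9)
  # far away only background
  expect_equal(ph$vol[1, 24, 24], 10, tolerance = 1e-9)
  # a radius-distant voxel has an intermediate partial-volume value
  expect_true(any(ph$vol > 20 & ph$vol < 90))
  expect_false(ph$truth$overlap)
  expect_equal(ph$truth$radii$radius_mm, 1.6)
})

test_that("the cohort has the requested design and planted shifts", {
  sp <- cohort_spec(metrics = c("m1", "m2"),
                    effects = list(m1 = c(0, -1, -2)),
                    rater_sd = 0.1, rater_vars = "m1", seed = 8)
  co <- make_cohort(sp)
  expect_identical(nrow(co), 107L)
  expect_identical(as.vector(table(co$group)), c(48L, 34L, 25L))
  expect_identical(levels(co$group), c("HC", "PD-NC", "PD-MCI"))
  expect_true(all(cognitive_tests() %in% names(co)))
  expect_true(all(c("age", "sex", "education", "updrs3", "gds") %in% names(co)))
  expect_true("m1_rater2" %in% names(co))
  expect_false("m2_rater2" %in% names(co))
  # planted ordering of medians
  med <- tapply(co$m1, co$group, median)
  expect_true(med["HC"] > med["PD-NC"] && med["PD-NC"] > med["PD-MCI"])
  # untouched metric shows no such separation of this size
  med2 <- tapply(co$m2, co$group, median)
  expect_lt(abs(med2["HC"] - med2["PD-MCI"]), 1)
})

test_that("the copula plants the requested Spearman correlation on average", {
  rhos <- sapply(1:10, function(s) {
    co <- make_cohort(cohort_spec(
      n_hc = 3, n_pdnc = 3, n_pdmci = 500, metrics = "m1",
      target_rho = list(metric = "m1", score = "MMSE", group = "PD-MCI",
                        rho = 0.7), seed = s))
    sub <- co[co$group == "PD-MCI", ]
    cor(sub$m1, sub$MMSE, method = "spearman")
  })
  expect_lt(abs(mean(rhos) - 0.7), 0.05)
})

test_that("make_atlas partitions the mask into the requested labels", {
  at <- make_atlas(c(10, 10, 6), n_labels = 4, seed = 2)
  expect_identical(sort(unique(as.vector(at$labels))), 1:4)
  expect_true(all(at$labels > 0))
  expect_identical(nrow(at$table), 4L)
  # masked version labels only the foreground
  mask <- array(0L, dim = c(10, 10, 6)); mask[3:8, 3:8, 2:5] <- 1L
  atm <- make_atlas(c(10, 10, 6), n_labels = 3, seed = 2, mask = mask)
  expect_true(all(atm$labels[mask == 0] == 0))
  expect_identical(sort(unique(as.vector(atm$labels[mask != 0]))), 1:3)
  expect_error(make_atlas(c(2, 2, 1), n_labels = 10), "labels")
})
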