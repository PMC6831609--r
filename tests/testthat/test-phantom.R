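test_that("calibration reproduces its targets through independent oracles", {
  p <- calibrate_kinetics(0.92, 0.085, 29.89, 17.12)
  expect_equal(oracle_peak(p)$peak_density, 0.92, tolerance = 1e-6)
  expect_equal(oracle_max_slope(p)$max_slope, 0.085, tolerance = 1e-6)
  expect_equal(oracle_integral(p, 0, 50), 29.89, tolerance = 1e-6)
})

test_that("calibration is a fixed point on self-derived targets", {
  p0 <- gv_params(A = 0.1, t0 = 2, alpha = 2.5, beta = 3)
  targets <- c(gv_peak(p0)$peak_density, gv_max_slope(p0)$max_slope,
               gv_integral(p0, 0, 50))
  p1 <- calibrate_kinetics(targets[1], targets[2], targets[3],
                           gv_peak(p0)$t_peak)
  expect_equal(gv_peak(p1)$peak_density, targets[1], tolerance = 1e-6)
  expect_equal(gv_max_slope(p1)$max_slope, targets[2], tolerance = 1e-6)
  expect_equal(gv_integral(p1, 0, 50), targets[3], tolerance = 1e-6)
})

test_that("infeasible calibration targets raise a named failure", {
  expect_error(calibrate_kinetics(1, 100, 1, 1), "calibration failure")
  # mean upslope to the peak exceeding the max slope is impossible
  expect_error(calibrate_kinetics(1, 0.05, 30, 17), "mean upslope")
  expect_error(calibrate_kinetics(-1, 1, 1, 1), "calibration failure")
})

test_that("the default phantom carries the published ground truth", {
  spec <- default_phantom(grid = 64, noise_sigma = 0)
  truth <- lapply(spec$regions, function(r) r$kinetics)
  names(truth) <- vapply(spec$regions, `[[`, "", "label")

  myo <- truth$myocardium
  expect_equal(gv_peak(myo)$peak_density - myo$baseline, 0.92,
               tolerance = 1e-6)
  expect_equal(myo$baseline, 0.16)
  expect_equal(gv_max_slope(truth$descending_aorta)$max_slope, 1.232,
               tolerance = 1e-6)
  expect_equal(gv_integral(truth$left_ventricle, 0, 50), 96.77,
               tolerance = 1e-6)

  # masks are pairwise disjoint and non-empty
  masks <- region_masks(spec)
  expect_true(all(vapply(masks, sum, 0) > 0))
  overlap <- Reduce(`+`, lapply(masks, as.numeric))
  expect_true(all(overlap <= 1))
})

test_that("noiseless rendering reproduces the analytic curves", {
  k <- gv_params(A = 0.05, t0 = 2, alpha = 2.5, beta = 4, baseline = 0.16)
  t_peak <- gv_peak(k)$t_peak
  # acquisition whose frame times include the analytic peak time
  acq <- acquisition_spec(n_frames = 12L, total_duration = 26,
                          retained_indices = 1:12,
                          snap_times = t_peak, noise_sigma = 0)
  spec <- phantom_spec(
    list(region_spec("myocardium", center = c(12, 12), radius = 6,
                     kinetics = k, recirculation_scale = 0)),
    grid = 24L, acquisition = acq)
  r <- render_series(spec)
  f_pk <- which(abs(r$series$frame_times - t_peak) < 1e-9)
  inside <- which(r$masks$myocardium, arr.ind = TRUE)[1, ]
  outside <- c(1, 1)
  # background pixels carry exactly the zero baseline in every frame
  expect_identical(r$series$frames[, outside[1], outside[2]],
                   rep(0, 12))
  # region pixel at the peak frame equals baseline + peak enhancement
  expect_equal(r$series$frames[f_pk, inside[1], inside[2]],
               gv_peak(k)$peak_density, tolerance = 1e-12)
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- default_phantom(grid = 32, noise_sigma = 0.05, seed = 99)
  a <- render_series(spec)
  b <- render_series(spec)
  expect_identical(a$series$frames, b$series$frames)
  c_ <- render_series(spec, seed = 100)
  expect_false(identical(a$series$frames, c_$series$frames))
})

test_that("rendered noise has the specified moments", {
  sigma <- 0.05
  spec0 <- default_phantom(grid = 64, noise_sigma = 0)
  specn <- default_phantom(grid = 64, noise_sigma = sigma, seed = 3)
  res <- render_series(specn)$series$frames -
    render_series(spec0)$series$frames
  n <- length(res)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(res)), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(res) - sigma), 3 * sigma / sqrt(2 * n))
})

test_that("acquisition defaults give 15 retained non-equidistant points", {
  acq <- acquisition_spec()
  expect_equal(acq$n_frames, 36L)
  expect_equal(acq$total_duration, 26)
  tt <- acq$frame_times[acq$retained_indices]
  expect_length(tt, 15L)
  expect_true(all(c(7.5, 10.9, 23.3, 24.9) %in% tt))
  expect_gt(length(unique(round(diff(tt), 6))), 1)  # non-equidistant
  expect_true(all(diff(acq$frame_times) > 0))
})

test_that("region and acquisition invariants are enforced", {
  k <- gv_params(1, 0, 2, 3)
  expect_error(region_spec("x", c(5, 5), radius = 2, kinetics = k,
                           recirculation_scale = 1.2), "recirculation")
  expect_error(region_spec("x", c(5, 5), radius = 2, kinetics = k,
                           recirculation_scale = 0.2,
                           recirculation_delay = 10), "12")
  expect_error(acquisition_spec(noise_sigma = -1), "noise_sigma")
  expect_error(acquisition_spec(retained_indices = c(0, 5)), "range")
  # overlapping regions are rejected
  expect_error(phantom_spec(
    list(region_spec("a", c(10, 10), radius = 4, kinetics = k),
         region_spec("b", c(12, 10), radius = 4, kinetics = k)),
    grid = 24L), "overlap")
  # region outside the grid is rejected
  expect_error(phantom_spec(
    list(region_spec("a", c(2, 2), radius = 6, kinetics = k)),
    grid = 24L), "fit the grid")
})
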