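# one shared noiseless end-to-end run on a reduced grid
noiseless_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- default_phantom(grid = 48, noise_sigma = 0)
      r <- render_series(spec)
      ff <- fit_field(r$series)
      cache <<- list(spec = spec, render = r, fits = ff,
                     maps = compute_maps(ff))
    }
    cache
  }
})

test_that("pixel-wise fitting converges inside regions and not outside", {
  run <- noiseless_run()
  inside <- Reduce(`|`, run$render$masks)
  expect_true(all(run$fits$converged[inside]))
  expect_false(any(run$fits$converged[!inside]))  # flat background

  # field fitting equals independent per-pixel fitting
  px <- which(run$render$masks$myocardium, arr.ind = TRUE)[1, ]
  f <- fit_first_pass(pixel_curve(run$render$series, px[1], px[2]))
  expect_equal(run$fits$alpha[px[1], px[2]], f$params$alpha)
  expect_equal(run$fits$r_squared[px[1], px[2]], f$r_squared)
})

test_that("maps recover the analytic ground truth within 2 percent", {
  run <- noiseless_run()
  truth <- run$render$truth
  for (q in c("peak_enhancement", "perfusion", "time_to_peak", "volume")) {
    for (nm in names(run$render$masks)) {
      m <- run$render$masks[[nm]]
      got <- median(run$maps[[q]][m & run$maps$valid_mask])
      want <- median(truth[[q]][m])
      expect_lt(abs(got - want) / want, 0.02)
    }
  }
})

test_that("maps are non-negative where valid and NaN where invalid", {
  run <- noiseless_run()
  for (q in c("peak_enhancement", "perfusion", "time_to_peak", "volume")) {
    expect_true(all(run$maps[[q]][run$maps$valid_mask] >= 0))
    expect_true(all(is.nan(run$maps[[q]][!run$maps$valid_mask])))
  }
})

test_that("the density floor invalidates weakly enhancing pixels", {
  # peak density 0.4 mg/ml < 0.55 floor -> excluded from the maps
  weak <- calibrate_kinetics(0.4, 0.08, 10, 8)
  spec <- disk_phantom(weak)
  r <- render_series(spec)
  maps <- compute_maps(fit_field(r$series))
  m <- r$masks$myocardium
  expect_false(any(maps$valid_mask[m]))
  expect_true(all(is.nan(maps$peak_enhancement[m])))
  # same phantom, lower floor: the same pixels are valid
  maps2 <- compute_maps(fit_field(r$series), density_floor = 0.3)
  expect_true(all(maps2$valid_mask[m]))
})

test_that("a series with no enhancement yields all-invalid maps", {
  frames <- array(0.16, c(15, 8, 8))
  s <- dynamic_series(frames, retained_times())
  maps <- compute_maps(fit_field(s))
  expect_false(any(maps$valid_mask))
  expect_true(all(is.nan(maps$peak_enhancement)))
})

test_that("fit_field rejects series with too few frames", {
  s <- dynamic_series(array(1, c(4, 4, 4)), 1:4)
  expect_error(fit_field(s), "at least 5")
})

test_that("median filter matches examples and the brute-force oracle", {
  const <- matrix(2.5, 7, 7)
  expect_equal(median_filter3(const), const)

  outl <- const; outl[4, 4] <- 40
  expect_equal(median_filter3(outl), const)

  # idempotence on piecewise-constant regions wider than the kernel
  pc <- cbind(matrix(1, 9, 5), matrix(4, 9, 6))
  expect_identical(median_filter3(median_filter3(pc)), median_filter3(pc))

  # bit-identical to the naive double loop, including NaN handling
  set.seed(5)
  for (i in 1:5) {
    m <- matrix(rnorm(11 * 13), 11, 13)
    m[sample(length(m), 20)] <- NaN
    expect_identical(median_filter3(m), naive_median3(m))
  }
})

test_that("smoothing preserves the validity mask and invalid pixels", {
  run <- noiseless_run()
  sm <- smooth_maps(run$maps)
  expect_identical(sm$valid_mask, run$maps$valid_mask)
  expect_true(all(is.nan(sm$peak_enhancement[!sm$valid_mask])))
  # a constant-valued region keeps its median through the filter
  m <- run$render$masks$left_ventricle
  expect_equal(median(sm$peak_enhancement[m]),
               median(run$maps$peak_enhancement[m]))
})

test_that("scaling densities scales amplitude maps, not time to peak", {
  k <- gv_params(A = 0.1, t0 = 2, alpha = 2.2, beta = 4, baseline = 0)
  spec <- disk_phantom(k, grid = 16L)
  r <- render_series(spec)
  kf <- 3
  scaled <- dynamic_series(r$series$frames * kf, r$series$frame_times)
  # volume_stop = 0 keeps the full 50-s window: the density stop criterion
  # is an absolute threshold and is deliberately not scale-equivariant
  m1 <- compute_maps(fit_field(r$series), density_floor = 0,
                     volume_stop = 0)
  m2 <- compute_maps(fit_field(scaled), density_floor = 0, volume_stop = 0)
  msk <- r$masks$myocardium
  expect_equal(median(m2$peak_enhancement[msk]),
               kf * median(m1$peak_enhancement[msk]), tolerance = 1e-3)
  expect_equal(median(m2$perfusion[msk]),
               kf * median(m1$perfusion[msk]), tolerance = 1e-3)
  expect_equal(median(m2$volume[msk]),
               kf * median(m1$volume[msk]), tolerance = 1e-3)
  expect_equal(median(m2$time_to_peak[msk]),
               median(m1$time_to_peak[msk]), tolerance = 1e-3)
})

test_that("ROI statistics reproduce region ratios and edge cases", {
  nanm <- matrix(1, 6, 6)
  maps <- perfusion_maps(
    peak_enhancement = matrix(c(rep(0.92, 18), rep(7.76, 18)), 6, 6),
    perfusion = matrix(0.085, 6, 6), time_to_peak = matrix(17, 6, 6),
    volume = matrix(29.9, 6, 6), valid_mask = matrix(TRUE, 6, 6))
  rois <- list(myocardium = cbind(matrix(TRUE, 6, 3), matrix(FALSE, 6, 3)),
               descending_aorta = cbind(matrix(FALSE, 6, 3),
                                        matrix(TRUE, 6, 3)))
  st <- roi_statistics(maps, rois, reference = "descending_aorta")
  pe_myo <- st[st$region == "myocardium" &
                 st$quantity == "peak_enhancement", ]
  expect_equal(pe_myo$median, 0.92)
  expect_equal(pe_myo$sd, 0)                      # identical pixels
  expect_equal(round(pe_myo$pct_of_reference, 2), 11.86)
  pe_ref <- st[st$region == "descending_aorta" &
                 st$quantity == "peak_enhancement", ]
  expect_equal(pe_ref$pct_of_reference, 100)      # self ratio

  expect_error(roi_statistics(maps, list(empty = matrix(FALSE, 6, 6))),
               "empty")
  expect_error(roi_statistics(maps, list(matrix(TRUE, 6, 6))), "named")
})

test_that("volume integration stops when the curve falls below threshold", {
  # fast washout: curve drops below 0.25 mg/ml well before 50 s
  fast <- gv_params(A = 1, t0 = 0, alpha = 3, beta = 1.5)
  t_stop <- iodineperf:::volume_window_end(fast, 50, 0.25)
  expect_lt(t_stop, 50)
  expect_equal(gv_eval(fast, t_stop), 0.25, tolerance = 1e-6)
  # slow washout (elevated baseline keeps density above threshold): full window
  slow <- gv_params(A = 0.0312, t0 = 0, alpha = 1.757, beta = 10.62,
                    baseline = 0.16)
  expect_equal(iodineperf:::volume_window_end(slow, 50, 0.25), 50)
})
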