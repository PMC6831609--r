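#' Pixel-wise first-pass fitting of a dynamic series
#'
#' Applies [fit_first_pass()] independently to every pixel's
#' time-enhancement curve. Per-pixel optimization failures are recorded in
#' the `converged` field, never raised, so a whole-image run always
#' completes.
#'
#' @param series a [dynamic_series] with at least 5 frames.
#' @inheritParams fit_first_pass
#' @return Object of class `fit_field`: matrices `A`, `t0`, `alpha`,
#'   `beta`, `baseline`, `r_squared`, `preliminary_peak_time` (numeric,
#'   `NA` where not converged), `n_points_used` (integer), `converged` and
#'   `step2_fallback` (logical), plus `frame_times` and `pixel_spacing`.
#' @export
fit_field <- function(series, recirculation_cut = 12,
                      bounds = list(A = c(1e-8, 100), t0 = c(0, Inf),
                                    alpha = c(0.1, 20), beta = c(0.05, 60)),
                      ftol = 1e-10) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames)
  if (d[1L] < 5L)
    stop("pixel-wise fitting needs at least 5 frames", call. = FALSE)
  t <- series$frame_times
  num <- function() matrix(NA_real_, d[2L], d[3L])
  out <- list(A = num(), t0 = num(), alpha = num(), beta = num(),
              baseline = num(), r_squared = num(),
              preliminary_peak_time = num(),
              n_points_used = matrix(0L, d[2L], d[3L]),
              converged = matrix(FALSE, d[2L], d[3L]),
              step2_fallback = matrix(FALSE, d[2L], d[3L]),
              frame_times = t, pixel_spacing = series$pixel_spacing)
  for (j in seq_len(d[3L])) {
    for (i in seq_len(d[2L])) {
      y <- series$frames[, i, j]
      if (diff(range(y)) < 1e-12) next  # flat curve: nothing to fit
      f <- fit_first_pass(list(times = t, densities = y),
                          recirculation_cut = recirculation_cut,
                          bounds = bounds, ftol = ftol)
      out$r_squared[i, j] <- f$r_squared
      out$preliminary_peak_time[i, j] <- f$preliminary_peak_time
      out$n_points_used[i, j] <- f$n_points_used
      out$converged[i, j] <- f$converged
      out$step2_fallback[i, j] <- f$step2_fallback
      if (!is.null(f$params)) {
        out$A[i, j] <- f$params$A
        out$t0[i, j] <- f$params$t0
        out$alpha[i, j] <- f$params$alpha
        out$beta[i, j] <- f$params$beta
        out$baseline[i, j] <- f$params$baseline
      }
    }
  }
  structure(out, class = "fit_field")
}

# end of the volume integration window: min(window, first post-peak time
# the full fitted curve I0 + term drops below `stop`)
volume_window_end <- function(params, window = 50, stop = 0.25) {
  pk <- gv_peak(params)
  if (pk$t_peak >= window) return(window)
  if (gv_eval(params, window) >= stop) return(window)
  if (pk$peak_density < stop) return(pk$t_peak)
  stats::uniroot(function(t) gv_eval(params, t) - stop,
                 c(pk$t_peak, window), tol = 1e-10)$root
}

#' Assemble quantitative perfusion maps from a fit field
#'
#' Per converged pixel: peak enhancement is the fitted peak density minus
#' the baseline; perfusion is the maximal slope of the fitted curve; time
#' to peak is the fitted peak time on the acquisition clock (or relative to
#' bolus arrival `t0`, see `ttp_reference`); iodine volume is the integral
#' of the bolus term from 0 to `min(integration_window, first post-peak
#' time the fitted curve drops below volume_stop)`. A pixel is valid when
#' its fit converged and its fitted peak density (baseline + enhancement)
#' reaches `density_floor`; invalid pixels carry `NaN`.
#'
#' @param fits a [fit_field].
#' @param integration_window volume integration horizon, s (default 50).
#' @param density_floor validity threshold on peak iodine density, mg/ml
#'   (default 0.55).
#' @param volume_stop post-peak density stop criterion, mg/ml (default
#'   0.25).
#' @param window_end horizon (s) for the degenerate-shape slope search;
#'   defaults to `integration_window`.
#' @param ttp_reference `"scan_start"` (time to peak measured from the
#'   acquisition start) or `"bolus_arrival"` (from the fitted `t0`).
#' @return A [perfusion_maps].
#' @export
compute_maps <- function(fits, integration_window = 50, density_floor = 0.55,
                         volume_stop = 0.25, window_end = integration_window,
                         ttp_reference = c("scan_start", "bolus_arrival")) {
  stopifnot(inherits(fits, "fit_field"))
  ttp_reference <- match.arg(ttp_reference)
  dims <- dim(fits$A)
  nanm <- matrix(NaN, dims[1L], dims[2L])
  pe <- perf <- ttp <- vol <- nanm
  conv <- fits$converged & is.finite(fits$A)
  idx <- which(conv)
  for (i in idx) {
    p <- gv_params(fits$A[i], fits$t0[i], fits$alpha[i], fits$beta[i],
                   fits$baseline[i])
    pk <- gv_peak(p)
    pe[i] <- pk$peak_density - p$baseline
    perf[i] <- gv_max_slope(p, window = window_end)$max_slope
    ttp[i] <- if (ttp_reference == "scan_start") pk$t_peak
              else pk$t_peak - p$t0
    vol[i] <- gv_integral(
      p, 0, volume_window_end(p, integration_window, volume_stop))
  }
  valid <- conv
  valid[idx] <- fits$baseline[idx] + pe[idx] >= density_floor
  for (m in c("pe", "perf", "ttp", "vol")) {
    v <- get(m); v[!valid] <- NaN; assign(m, v)
  }
  perfusion_maps(pe, perf, ttp, vol, valid, r_squared = fits$r_squared,
                 pixel_spacing = fits$pixel_spacing)
}

#' 3 x 3 median filter with invalid-pixel exclusion
#'
#' Replaces each valid pixel by the median of the valid (finite) values in
#' its 3 x 3 neighborhood; edge neighborhoods are truncated at the image
#' border. Pixels that are `NaN`/`NA` on input stay invalid and never
#' contribute to a neighbor's median.
#'
#' @param m numeric matrix, possibly containing `NaN`.
#' @return Filtered matrix of the same shape.
#' @export
median_filter3 <- function(m) {
  stopifnot(is.matrix(m))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  stack <- matrix(NA_real_, nr * nc, 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    stack[, k] <- as.vector(pad[di + seq_len(nr), dj + seq_len(nc)])
  }
  out <- apply(stack, 1L, stats::median, na.rm = TRUE)
  out[!is.finite(as.vector(m))] <- NaN  # invalid stays invalid
  out[!is.finite(out)] <- NaN           # fully-invalid neighborhoods
  matrix(out, nr, nc)
}

#' Median-filter smoothing of perfusion maps
#'
#' Applies the 3 x 3 median filter ([median_filter3()]) to each of the four
#' quantitative maps to damp pixel-wise fitting noise. Invalid pixels are
#' excluded from every neighborhood median and remain invalid; the validity
#' mask is unchanged.
#'
#' @param maps a [perfusion_maps].
#' @return A smoothed [perfusion_maps].
#' @export
smooth_maps <- function(maps) {
  stopifnot(inherits(maps, "perfusion_maps"))
  out <- maps
  for (q in map_quantities) out[[q]] <- median_filter3(maps[[q]])
  out
}

#' Per-ROI summary statistics of perfusion maps
#'
#' Aggregates each quantitative map over named regions of interest,
#' reporting mean, median and sd of the valid pixels, and optionally each
#' region's median as a percentage of a reference region's median.
#'
#' @param maps a [perfusion_maps].
#' @param rois named list of logical masks (matrix shape of the maps).
#' @param reference optional name of the reference ROI for percentage
#'   ratios.
#' @return A long-format `data.frame` with columns `region`, `quantity`,
#'   `mean`, `median`, `sd`, `n_valid` and (if `reference` is given)
#'   `pct_of_reference`.
#' @export
roi_statistics <- function(maps, rois, reference = NULL) {
  stopifnot(inherits(maps, "perfusion_maps"), is.list(rois))
  if (is.null(names(rois)) || any(!nzchar(names(rois))))
    stop("'rois' must be a named list of masks", call. = FALSE)
  for (nm in names(rois)) {
    if (!identical(dim(rois[[nm]]), dim(maps$valid_mask)))
      stop("ROI '", nm, "' does not match the map shape", call. = FALSE)
    if (!any(rois[[nm]])) stop("ROI '", nm, "' is empty", call. = FALSE)
  }
  if (!is.null(reference) && !reference %in% names(rois))
    stop("reference ROI '", reference, "' not among 'rois'", call. = FALSE)
  rows <- list()
  med <- function(nm, q) {
    v <- maps[[q]][rois[[nm]] & maps$valid_mask]
    stats::median(v)
  }
  for (nm in names(rois)) {
    for (q in map_quantities) {
      v <- maps[[q]][rois[[nm]] & maps$valid_mask]
      rows[[length(rows) + 1L]] <- data.frame(
        region = nm, quantity = q,
        mean = if (length(v)) mean(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else if (length(v)) 0 else NA_real_,
        n_valid = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    refmed <- vapply(map_quantities, function(q) med(reference, q),
                     numeric(1))
    out$pct_of_reference <- 100 * out$median / refmed[out$quantity]
  }
  out
}
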