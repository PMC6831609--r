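#' Dynamic iodine-density image series
#'
#' The pipeline's image input: a stack of co-registered 2-D iodine-density
#' frames with per-frame acquisition timestamps.
#'
#' @param frames 3-D numeric array, time x rows x cols, mg/ml.
#' @param frame_times acquisition times, s; strictly increasing, one per
#'   frame.
#' @param pixel_spacing pixel edge length, mm.
#' @param units unit tag; the analysis requires `"mg/ml"`.
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, frame_times, pixel_spacing = 0.40,
                           units = "mg/ml") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D array (time x rows x cols)", call. = FALSE)
  if (dim(frames)[1L] != length(frame_times))
    stop("frame count (", dim(frames)[1L], ") does not match number of ",
         "frame_times (", length(frame_times), ")", call. = FALSE)
  if (any(!is.finite(frame_times)) || any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(frames)))
    stop("'frames' contains non-finite values", call. = FALSE)
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("'pixel_spacing' must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 pixel_spacing = pixel_spacing, units = units),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "dynamic series: %d frames of %d x %d px (%.2f mm), t = %.2f..%.2f s, %s\n",
    d[1], d[2], d[3], x$pixel_spacing, min(x$frame_times),
    max(x$frame_times), x$units))
  invisible(x)
}

#' Extract one pixel's time-enhancement curve
#'
#' @param series a [dynamic_series].
#' @param row,col 1-based pixel indices.
#' @return A [tec] object.
#' @export
pixel_curve <- function(series, row, col) {
  stopifnot(inherits(series, "dynamic_series"))
  tec(series$frame_times, series$frames[, row, col], units = series$units)
}

#' Quantitative perfusion map set
#'
#' Container for the four co-registered hemodynamic maps plus the validity
#' mask and the per-pixel goodness of fit. Invalid pixels carry `NaN` in all
#' quantitative maps (rendered black when exported).
#'
#' @param peak_enhancement mg/ml matrix.
#' @param perfusion mg/ml/s matrix.
#' @param time_to_peak s matrix.
#' @param volume mg/ml*s matrix.
#' @param valid_mask logical matrix.
#' @param r_squared per-pixel coefficient of determination.
#' @param pixel_spacing mm.
#' @return Object of class `perfusion_maps`.
#' @export
perfusion_maps <- function(peak_enhancement, perfusion, time_to_peak, volume,
                           valid_mask, r_squared = NULL,
                           pixel_spacing = 0.40) {
  dims <- dim(peak_enhancement)
  for (m in list(perfusion, time_to_peak, volume, valid_mask))
    if (!identical(dim(m), dims))
      stop("all maps must share one matrix shape", call. = FALSE)
  if (is.null(r_squared)) r_squared <- matrix(NA_real_, dims[1], dims[2])
  structure(list(peak_enhancement = peak_enhancement, perfusion = perfusion,
                 time_to_peak = time_to_peak, volume = volume,
                 valid_mask = valid_mask, r_squared = r_squared,
                 pixel_spacing = pixel_spacing),
            class = "perfusion_maps")
}

#' @export
print.perfusion_maps <- function(x, ...) {
  d <- dim(x$peak_enhancement)
  cat(sprintf("perfusion maps: %d x %d px, %d valid (%.1f%%)\n",
              d[1], d[2], sum(x$valid_mask),
              100 * mean(x$valid_mask)))
  for (q in c("peak_enhancement", "perfusion", "time_to_peak", "volume")) {
    v <- x[[q]][x$valid_mask]
    if (length(v))
      cat(sprintf("  %-16s median %.4g (range %.4g..%.4g)\n",
                  q, stats::median(v), min(v), max(v)))
  }
  invisible(x)
}

map_quantities <- c("peak_enhancement", "perfusion", "time_to_peak", "volume")
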