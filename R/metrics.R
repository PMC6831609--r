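#' ROI sample of one image channel at one timepoint
#'
#' Mean signal and standard deviation within a region of interest of a
#' given reconstruction channel (conventional HU, virtual mono-energetic,
#' or iodine density) at one acquisition time. These are the ingredients of
#' the temporal contrast metrics.
#'
#' @param mean_signal ROI mean, channel units (HU or mg/ml).
#' @param sd ROI standard deviation, same units; >= 0.
#' @param roi_area ROI area, mm^2; > 0.
#' @param timepoint acquisition time, s.
#' @param channel channel tag, e.g. `"iodine_density"`, `"monoE40"`,
#'   `"conventional"`.
#' @return Object of class `roi_sample`.
#' @export
roi_sample <- function(mean_signal, sd, roi_area = 50, timepoint = NA_real_,
                       channel = "iodine_density") {
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (roi_area <= 0) stop("'roi_area' must be > 0", call. = FALSE)
  structure(list(mean_signal = mean_signal, sd = sd, roi_area = roi_area,
                 timepoint = timepoint, channel = channel),
            class = "roi_sample")
}

#' ROI sample measured from a dynamic series
#'
#' @param series a [dynamic_series].
#' @param mask logical ROI matrix.
#' @param frame frame index (1-based).
#' @param channel channel tag for the resulting sample.
#' @return A [roi_sample] whose area follows the mask and pixel spacing.
#' @export
roi_sample_from_series <- function(series, mask, frame,
                                   channel = "iodine_density") {
  stopifnot(inherits(series, "dynamic_series"))
  v <- series$frames[frame, , ][mask]
  if (!length(v)) stop("empty ROI", call. = FALSE)
  roi_sample(mean(v), stats::sd(v),
             roi_area = sum(mask) * series$pixel_spacing^2,
             timepoint = series$frame_times[frame], channel = channel)
}

check_channels <- function(early, late) {
  stopifnot(inherits(early, "roi_sample"), inherits(late, "roi_sample"))
  if (!identical(early$channel, late$channel))
    stop("ROI samples come from different channels (", early$channel,
         " vs ", late$channel, ")", call. = FALSE)
}

#' Relative increase in signal (RIS)
#'
#' `(S_late - S_early) / S_early`: the fractional signal change of a region
#' between the pre-contrast and the contrast-saturated timepoint. Unitless;
#' multiply by 100 for percent.
#'
#' @param early,late [roi_sample]s of the same channel.
#' @return Dimensionless ratio.
#' @export
relative_signal_increase <- function(early, late) {
  check_channels(early, late)
  if (early$mean_signal == 0)
    stop("relative signal increase is undefined for zero early signal",
         call. = FALSE)
  (late$mean_signal - early$mean_signal) / early$mean_signal
}

#' Temporal contrast-to-noise ratio (CNR)
#'
#' `(S_late - S_early) / sqrt(sd_late^2 + sd_early^2)`: the temporal signal
#' change in units of the combined ROI noise.
#'
#' @inheritParams relative_signal_increase
#' @return Dimensionless ratio.
#' @export
temporal_cnr <- function(early, late) {
  check_channels(early, late)
  denom <- sqrt(early$sd^2 + late$sd^2)
  if (denom == 0)
    stop("temporal CNR is undefined when both ROI sds are zero",
         call. = FALSE)
  (late$mean_signal - early$mean_signal) / denom
}

#' Pixel count of an ROI area
#'
#' Number of pixels covering a physical ROI area at a given pixel spacing,
#' rounded half-to-even (a 50 mm^2 ROI at 0.40 mm spacing is 312.5 pixels,
#' reported as 312).
#'
#' @param area_mm2 ROI area, mm^2.
#' @param pixel_spacing pixel edge length, mm.
#' @return Integer pixel count.
#' @export
roi_pixels <- function(area_mm2, pixel_spacing) {
  if (area_mm2 <= 0 || pixel_spacing <= 0)
    stop("'area_mm2' and 'pixel_spacing' must be > 0", call. = FALSE)
  as.integer(round(area_mm2 / pixel_spacing^2))
}
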