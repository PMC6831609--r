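# sidecar path next to an image file (.nii, .nii.gz, .tif, .tiff)
sidecar_path <- function(path) {
  base <- sub("\\.(nii\\.gz|nii|tiff?|TIFF?)$", "", path)
  paste0(base, ".json")
}

is_tiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

#' Write a dynamic series to disk
#'
#' Writes the frame stack as a 3-D NIfTI volume (rows x cols x time) or a
#' multi-page TIFF, plus a JSON sidecar carrying the acquisition metadata
#' (`frame_times_s`, `pixel_spacing_mm`, `units`). TIFF pages are stored
#' normalized to `[0, 1]`; the normalization constant is recorded in the
#' sidecar as `value_scale`.
#'
#' @param series a [dynamic_series].
#' @param path output file ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  meta <- list(frame_times_s = series$frame_times,
               pixel_spacing_mm = series$pixel_spacing,
               units = series$units)
  if (is_tiff(path)) {
    scale <- max(abs(series$frames), 1e-12)
    meta$value_scale <- scale
    pages <- lapply(seq_len(dim(series$frames)[1L]),
                    function(f) pmin(pmax(series$frames[f, , ] / scale, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    RNifti::writeNifti(RNifti::asNifti(aperm(series$frames, c(2, 3, 1))),
                       path)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dynamic series from disk
#'
#' Reads a 3-D NIfTI volume (time as the third axis) or a multi-page TIFF
#' together with its JSON sidecar, validating frame count, time
#' monotonicity and units (`"mg/ml"` iodine density is required — this
#' pipeline quantifies iodine concentration, not Hounsfield units).
#'
#' @param path image file written by [write_series()] (or compatible).
#' @return A [dynamic_series].
#' @export
read_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar '", sc,
         "' (expected fields frame_times_s, pixel_spacing_mm, units)",
         call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("frame_times_s", "pixel_spacing_mm", "units"))
    if (is.null(meta[[f]]))
      stop("sidecar is missing field '", f, "'", call. = FALSE)
  if (!identical(meta$units, "mg/ml"))
    stop("series units are '", meta$units, "'; this pipeline requires ",
         "iodine-density input in 'mg/ml' (convert dual-energy ",
         "reconstructions to iodine density first)", call. = FALSE)
  if (is_tiff(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    scale <- if (!is.null(meta$value_scale)) meta$value_scale else 1
    frames <- array(0, c(length(pages), nrow(pages[[1L]]),
                         ncol(pages[[1L]])))
    for (f in seq_along(pages)) frames[f, , ] <- pages[[f]] * scale
  } else {
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) != 3L)
      stop("expected a 3-D volume with time as the third axis",
           call. = FALSE)
    frames <- aperm(vol, c(3, 1, 2))
  }
  if (dim(frames)[1L] != length(meta$frame_times_s))
    stop("frame count (", dim(frames)[1L], ") does not match sidecar ",
         "frame_times_s (", length(meta$frame_times_s), ")", call. = FALSE)
  if (any(diff(meta$frame_times_s) <= 0))
    stop("sidecar frame_times_s must be strictly increasing",
         call. = FALSE)
  dynamic_series(frames, meta$frame_times_s,
                 pixel_spacing = meta$pixel_spacing_mm, units = meta$units)
}

# one 2-D map to disk in the series format
write_map_image <- function(m, path) {
  if (is_tiff(path)) {
    mm <- m; mm[!is.finite(mm)] <- 0
    scale <- max(abs(mm), 1e-12)
    tiff::writeTIFF(pmin(pmax(mm / scale, 0), 1), path,
                    bits.per.sample = 32L)
    jsonlite::write_json(list(value_scale = scale, invalid = "stored as 0"),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    RNifti::writeNifti(RNifti::asNifti(m), path)
  }
  invisible(path)
}

#' Write perfusion-map outputs
#'
#' Writes the four quantitative maps and the validity mask as images, the
#' per-region report as CSV (columns `Region`, `PeakEnhancement_mg_ml`,
#' `Perfusion_mg_ml_s`, `TimeToPeak_s`, `Volume_mg_ml_s`; one row per
#' region, medians of valid pixels), and a JSON run manifest recording the
#' configuration, seed and software version.
#'
#' @param maps a [perfusion_maps].
#' @param report long-format ROI statistics from [roi_statistics()] (or
#'   `NULL` for a header-only CSV).
#' @param dir output directory (created if absent).
#' @param format `"nifti"` or `"tiff"` map image format.
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional seed echoed into the manifest.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(maps, report = NULL, dir, format = c("nifti", "tiff"),
                          config = NULL, seed = NULL) {
  stopifnot(inherits(maps, "perfusion_maps"))
  format <- match.arg(format)
  ext <- if (format == "tiff") ".tif" else ".nii.gz"
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (q in map_quantities) {
    p <- file.path(dir, paste0(q, ext))
    write_map_image(maps[[q]], p)
    paths[q] <- p
  }
  p <- file.path(dir, paste0("valid_mask", ext))
  write_map_image(maps$valid_mask + 0, p)
  paths["valid_mask"] <- p

  csv <- file.path(dir, "report.csv")
  cols <- c(Region = NA, PeakEnhancement_mg_ml = "peak_enhancement",
            Perfusion_mg_ml_s = "perfusion", TimeToPeak_s = "time_to_peak",
            Volume_mg_ml_s = "volume")
  if (is.null(report) || !nrow(report)) {
    wide <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                 dimnames = list(NULL, names(cols))))
  } else {
    regions <- unique(report$region)
    wide <- data.frame(Region = regions, stringsAsFactors = FALSE)
    for (i in seq_along(cols)[-1]) {
      wide[[names(cols)[i]]] <- vapply(regions, function(rg) {
        v <- report$median[report$region == rg & report$quantity == cols[i]]
        if (length(v)) v else NA_real_
      }, numeric(1))
    }
  }
  utils::write.csv(wide, csv, row.names = FALSE)
  paths["report"] <- csv

  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(software = "iodineperf",
         version = as.character(utils::packageVersion("iodineperf")),
         config = config, seed = seed,
         written = as.list(paths)),
    manifest, auto_unbox = TRUE, digits = NA, null = "null")
  paths["manifest"] <- manifest
  invisible(paths)
}

gv_params_to_list <- function(k)
  list(A = k$A, t0 = k$t0, alpha = k$alpha, beta = k$beta,
       baseline = k$baseline)

#' Serialize a phantom specification to YAML
#'
#' @param spec a [phantom_spec].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
phantom_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  acq <- spec$acquisition
  obj <- list(
    grid = spec$grid,
    acquisition = list(n_frames = acq$n_frames,
                       total_duration = acq$total_duration,
                       frame_times = acq$frame_times,
                       retained_indices = acq$retained_indices,
                       pixel_spacing = acq$pixel_spacing,
                       noise_sigma = acq$noise_sigma, seed = acq$seed),
    regions = lapply(spec$regions, function(r)
      list(label = r$label, center = r$center, radius = r$radius,
           inner = r$inner, outer = r$outer,
           kinetics = gv_params_to_list(r$kinetics),
           recirculation_scale = r$recirculation_scale,
           recirculation_delay = r$recirculation_delay)))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' @param path YAML file written by [phantom_to_yaml()].
#' @return A [phantom_spec].
#' @export
phantom_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  acq <- do.call(acquisition_spec, obj$acquisition)
  regions <- lapply(obj$regions, function(r) {
    k <- do.call(gv_params, r$kinetics)
    region_spec(label = r$label, center = unlist(r$center),
                radius = r$radius, inner = r$inner, outer = r$outer,
                kinetics = k,
                recirculation_scale = r$recirculation_scale,
                recirculation_delay = r$recirculation_delay)
  })
  phantom_spec(regions, grid = obj$grid, acquisition = acq)
}
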