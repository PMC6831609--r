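#' Cumulative CT dose index of a dynamic protocol
#'
#' @param n_scans number of acquired scans (>= 0).
#' @param per_scan CTDIvol per scan, mGy (>= 0).
#' @return Total CTDIvol, mGy.
#' @examples
#' cumulative_ctdivol(15, 9)  # full dynamic protocol
#' cumulative_ctdivol(2, 9)   # two-shot protocol
#' @export
cumulative_ctdivol <- function(n_scans, per_scan) {
  if (n_scans < 0 || per_scan < 0)
    stop("'n_scans' and 'per_scan' must be >= 0", call. = FALSE)
  n_scans * per_scan
}

#' Iodine load per kilogram body weight
#'
#' Contrast-agent iodine dose normalized to body weight:
#' `volume_ml * concentration_mg_per_ml / weight_kg`. The reported value is
#' rounded half-away-from-zero to the nearest integer, matching clinical
#' reporting convention; the exact value is retained.
#'
#' @param volume_ml injected contrast volume, ml (>= 0).
#' @param concentration_mg_per_ml iodine content of the agent, mg/ml (> 0).
#' @param weight_kg body weight, kg (> 0).
#' @return List with `exact` and integer `reported`, both mg/kg.
#' @examples
#' iodine_load_per_kg(40, 300, 78)$reported  # 154
#' @export
iodine_load_per_kg <- function(volume_ml, concentration_mg_per_ml,
                               weight_kg) {
  if (weight_kg <= 0)
    stop("'weight_kg' must be > 0", call. = FALSE)
  if (volume_ml < 0 || concentration_mg_per_ml <= 0)
    stop("contrast volume and concentration must be positive",
         call. = FALSE)
  exact <- volume_ml * concentration_mg_per_ml / weight_kg
  list(exact = exact, reported = as.integer(floor(exact + 0.5)))
}
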