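#' Time-enhancement curve
#'
#' One pixel's or ROI's iodine density versus acquisition time. Times may be
#' non-equidistant (dynamic cardiac acquisitions routinely drop
#' motion-corrupted frames).
#'
#' @param times acquisition times, s; strictly increasing, length >= 5.
#' @param densities iodine densities, mg/ml; same length, finite.
#' @param units unit tag; only `"mg/ml"` is meaningful downstream.
#' @return Object of class `tec`.
#' @export
tec <- function(times, densities, units = "mg/ml") {
  if (length(times) < 5L)
    stop("a time-enhancement curve needs at least 5 points", call. = FALSE)
  if (length(times) != length(densities))
    stop("'times' and 'densities' must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("'times' must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(densities)))
    stop("'densities' must be finite", call. = FALSE)
  structure(list(times = as.numeric(times),
                 densities = as.numeric(densities),
                 units = units),
            class = "tec")
}

# deterministic baseline estimate: mean of the samples preceding the first
# sample that exceeds (initial estimate + 3 * robust sd); seeded from the
# first sample so fast-rising curves (ventricles) are not mistaken for
# elevated baselines
estimate_baseline <- function(y) {
  b0 <- y[1L]
  rsd <- stats::mad(diff(y)) / sqrt(2)
  if (!is.finite(rsd) || rsd == 0) rsd <- max(1e-6, 1e-3 * diff(range(y)))
  onset <- which(y > b0 + 3 * rsd)[1L]
  if (is.na(onset) || onset <= 1L) return(b0)
  mean(y[seq_len(onset - 1L)])
}

# deterministic start values: t0 from the 10%-of-range crossing, then
# alpha/beta/A by log-linearization of log(y - I0) in log(t - t0), (t - t0)
# over the rising limb (washout samples can carry recirculation and are
# left out of the initialization)
gv_start_values <- function(t, y, baseline) {
  rng <- max(y) - baseline
  i_pk <- which.max(y)
  below <- which(y < baseline + 0.1 * rng)
  below <- below[below < i_pk]
  t0 <- if (length(below)) t[max(below)] else t[1L]
  t0 <- max(0, t0)
  keep <- which(t > t0 & seq_along(t) <= i_pk & (y - baseline) > 0.05 * rng)
  alpha <- 2; beta <- NA_real_; A <- NA_real_
  if (length(keep) >= 3L) {
    dt <- t[keep] - t0
    fit <- tryCatch(stats::lm.fit(cbind(1, log(dt), dt),
                                  log(y[keep] - baseline)),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      alpha <- fit$coefficients[2L]
      beta <- -1 / fit$coefficients[3L]
      A <- exp(fit$coefficients[1L])
    }
  }
  alpha <- min(max(alpha, 0.2), 15)
  if (!is.finite(beta) || beta <= 0) beta <- max((t[i_pk] - t0) / alpha, 0.5)
  beta <- min(max(beta, 0.1), 50)
  if (!is.finite(A) || A <= 0)
    A <- rng / ((alpha * beta)^alpha * exp(-alpha))
  A <- min(max(A, 1e-8), 99)
  list(A = A, t0 = t0, alpha = alpha, beta = beta, baseline = baseline)
}

# analytic Jacobian of the residuals wrt (A, t0, alpha, beta, baseline)
gv_jacobian <- function(p, t) {
  dt <- t - p[2]
  pos <- dt > 0
  J <- matrix(0, length(t), 5L)
  d <- dt[pos]
  term <- p[1] * d^p[3] * exp(-d / p[4])
  J[pos, 1L] <- term / p[1]
  J[pos, 2L] <- -term * (p[3] / d - 1 / p[4])
  J[pos, 3L] <- term * log(d)
  J[pos, 4L] <- term * d / p[4]^2
  J[, 5L] <- 1
  J
}

# one bounded Levenberg-Marquardt pass with analytic derivatives;
# returns NULL on failure
gv_nls <- function(t, y, start, bounds, ftol) {
  lower <- c(bounds$A[1], bounds$t0[1], bounds$alpha[1], bounds$beta[1], 0)
  upper <- c(bounds$A[2], min(bounds$t0[2], max(t)), bounds$alpha[2],
             bounds$beta[2], max(max(y), 1e-6))
  st <- pmin(pmax(unlist(start), lower), upper)
  names(st) <- c("A", "t0", "alpha", "beta", "baseline")
  model <- function(p) p[5] + gv_term(p[1], p[2], p[3], p[4], t)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(
      par = st, lower = lower, upper = upper,
      fn = function(p) model(p) - y,
      jac = function(p) gv_jacobian(p, t),
      control = minpack.lm::nls.lm.control(
        ftol = ftol, ptol = ftol, maxiter = 300))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  cf <- fit$par
  # a shape/amplitude parameter pinned to its box is a failed fit, not an
  # estimate; t0 = 0 and baseline = 0 are legitimate interior physics
  kin_lower <- lower[c(1, 3, 4)]; kin_upper <- upper[c(1, 3, 4)]
  kin <- cf[c("A", "alpha", "beta")]
  at_bound <- any(kin - kin_lower < 1e-8 * pmax(1, abs(kin_lower))) ||
    any(kin_upper - kin < 1e-8 * pmax(1, abs(kin_upper)))
  list(coef = cf, at_bound = at_bound, fitted = model(cf))
}

#' Two-step first-pass gamma-variate fit
#'
#' Fits the gamma-variate bolus model (with an explicit baseline term) to a
#' time-enhancement curve in two steps: a first nonlinear least-squares fit
#' over all points yields a preliminary peak time; the second fit discards
#' samples later than `preliminary peak + recirculation_cut` seconds, so the
#' delayed second pass of recirculating contrast agent does not bias the
#' first-pass parameters. If the exclusion leaves fewer than 5 points the
#' step-1 fit is kept and flagged.
#'
#' Optimization failures are reported via `converged = FALSE`, never as
#' errors, so pixel-wise mapping over whole images cannot abort.
#'
#' @param curve a [tec] object (or list with `times`/`densities`).
#' @param recirculation_cut seconds beyond the preliminary peak after which
#'   samples are treated as recirculation and dropped (default 12).
#' @param bounds named list of `c(lower, upper)` box constraints for `A`,
#'   `t0`, `alpha`, `beta`.
#' @param ftol optimizer convergence tolerance.
#' @return Object of class `gv_fit`: `params` ([gv_params] or `NULL`),
#'   `r_squared`, `n_points_used`, `preliminary_peak_time`, `converged`,
#'   `step2_fallback`.
#' @export
fit_first_pass <- function(curve, recirculation_cut = 12,
                           bounds = list(A = c(1e-8, 100), t0 = c(0, Inf),
                                         alpha = c(0.1, 20),
                                         beta = c(0.05, 60)),
                           ftol = 1e-10) {
  if (!inherits(curve, "tec")) curve <- tec(curve$times, curve$densities)
  t <- curve$times; y <- curve$densities
  failed <- function() structure(
    list(params = NULL, r_squared = NA_real_, n_points_used = 0L,
         preliminary_peak_time = NA_real_, converged = FALSE,
         step2_fallback = FALSE),
    class = "gv_fit")

  if (diff(range(y)) < 1e-12) return(failed())   # flat: nothing to fit
  baseline0 <- max(0, estimate_baseline(y))
  if (max(y) - baseline0 <= 0) return(failed())
  start <- gv_start_values(t, y, baseline0)

  # deterministic multistart: if the primary start leaves unexplained
  # variance, retry from a coarse family of shapes and keep the best fit
  ss_tot_all <- sum((y - mean(y))^2)
  dev_of <- function(s) if (is.null(s)) Inf else sum((y - s$fitted)^2)
  s1 <- gv_nls(t, y, start, bounds, ftol)
  if (dev_of(s1) > 1e-6 * ss_tot_all) {
    i_pk <- which.max(y)
    rng <- max(y) - baseline0
    for (a0 in c(1.5, 3, 6)) {
      b0 <- max((t[i_pk] - start$t0) / a0, 0.2)
      alt <- list(A = rng / ((a0 * b0)^a0 * exp(-a0)), t0 = start$t0,
                  alpha = a0, beta = b0, baseline = baseline0)
      cand <- gv_nls(t, y, alt, bounds, ftol)
      if (is.null(cand)) next
      # prefer interior solutions, then lower deviance
      if (is.null(s1) ||
          (s1$at_bound && !cand$at_bound) ||
          (s1$at_bound == cand$at_bound && dev_of(cand) < dev_of(s1)))
        s1 <- cand
    }
  }
  if (is.null(s1)) return(failed())
  prelim_peak <- s1$coef[["t0"]] + s1$coef[["alpha"]] * s1$coef[["beta"]]

  keep <- t <= prelim_peak + recirculation_cut
  fallback <- sum(keep) < 5L
  if (fallback || all(keep)) {
    s2 <- s1
    keep <- rep(TRUE, length(t))
  } else {
    s2 <- gv_nls(t[keep], y[keep], as.list(s1$coef), bounds, ftol)
    if (is.null(s2)) { s2 <- s1; keep <- rep(TRUE, length(t)); fallback <- TRUE }
  }

  ss_res <- sum((y[keep] - s2$fitted)^2)
  ss_tot <- sum((y[keep] - mean(y[keep]))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  cf <- s2$coef
  params <- tryCatch(
    gv_params(cf[["A"]], cf[["t0"]], cf[["alpha"]], cf[["beta"]],
              cf[["baseline"]]),
    error = function(e) NULL)
  structure(
    list(params = params, r_squared = r2, n_points_used = sum(keep),
         preliminary_peak_time = unname(prelim_peak),
         converged = !is.null(params) && !s2$at_bound,
         step2_fallback = fallback),
    class = "gv_fit")
}

#' @export
print.gv_fit <- function(x, ...) {
  if (!x$converged) {
    cat("gamma-variate fit: not converged\n")
  } else {
    cat(sprintf(
      "gamma-variate fit: R^2 = %.5f, %d points used, preliminary peak %.2f s%s\n",
      x$r_squared, x$n_points_used, x$preliminary_peak_time,
      if (x$step2_fallback) " (step-2 fallback)" else ""))
    print(x$params)
  }
  invisible(x)
}
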