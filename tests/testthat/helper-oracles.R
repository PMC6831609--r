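# Independent numerical oracles for the gamma-variate closed forms.
# These deliberately avoid the package's analytic expressions: the peak is
# found by golden-section maximization, the maximal slope by maximizing a
# central-difference derivative, and the integral by adaptive quadrature.

oracle_peak <- function(p) {
  upper <- p$t0 + 3 * p$alpha * p$beta + 10
  opt <- stats::optimize(function(t) gv_eval(p, t),
                         interval = c(p$t0, upper), maximum = TRUE,
                         tol = 1e-12)
  list(t_peak = opt$maximum, peak_density = opt$objective)
}

oracle_max_slope <- function(p) {
  h <- 1e-6
  dslope <- function(t) (gv_eval(p, t + h) - gv_eval(p, t - h)) / (2 * h)
  upper <- p$t0 + p$alpha * p$beta  # slope max precedes the curve max
  opt <- stats::optimize(dslope, interval = c(p$t0 + 2 * h, upper),
                         maximum = TRUE, tol = 1e-12)
  list(t_max_slope = opt$maximum, max_slope = opt$objective)
}

oracle_integral <- function(p, t_start, t_end) {
  stats::integrate(function(t) gv_eval(p, t) - p$baseline, t_start, t_end,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# brute-force 3x3 median filter: explicit double loop over pixels and
# neighborhoods, skipping non-finite neighbors
naive_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NaN, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is.finite(m[i, j])) next
      vals <- c()
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              is.finite(m[ii, jj]))
            vals <- c(vals, m[ii, jj])
        }
      }
      if (length(vals)) out[i, j] <- stats::median(vals)
    }
  }
  out
}

# seeded generator of valid gamma-variate parameter sets in the regime the
# fit bounds cover
random_gv_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    gv_params(A = runif(1, 0.05, 5), t0 = runif(1, 0, 10),
              alpha = runif(1, 1.1, 8), beta = runif(1, 0.5, 10),
              baseline = runif(1, 0, 0.3)))
}
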