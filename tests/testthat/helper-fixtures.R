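# Shared fixtures and independent oracles for the test suite.

# The 6-pool parameter set used throughout: water and MT backgrounds plus
# the four labile bands.
six_pools <- function(rnoe16_amp = 0.01) {
  list(
    pool_spec(0.0, 0.85, 1.4, "water"),
    pool_spec(-2.5, 0.08, 25, "mt"),
    pool_spec(3.5, 0.03, 1.0, "amide"),
    pool_spec(2.0, 0.02, 1.5, "amine"),
    pool_spec(-3.5, 0.04, 1.5, "rnoe35"),
    pool_spec(-1.6, rnoe16_amp, 0.6, "rnoe16")
  )
}

# Brute-force per-offset Lorentzian-sum oracle, written independently of the
# package's vectorized evaluation: one scalar accumulation per offset.
lorentzian_sum_oracle <- function(pools, offsets) {
  out <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    acc <- 0
    for (p in pools) {
      hw <- p$fwhm / 2
      acc <- acc + p$amplitude * hw^2 / (hw^2 + (offsets[k] - p$center)^2)
    }
    out[k] <- 1 - acc
  }
  out
}

# Gaussian profile used to synthesize AREX inputs for the deconvolution
# tests without going through the package's own model code.
gauss_oracle <- function(x, A, mu, sigma) A * exp(-((x - mu)^2) / (2 * sigma^2))

# Wrap plain offset/value vectors as an AREX spectrum so deconvolution can
# be tested on exactly known inputs.
make_arex <- function(offsets, values, t1 = 1, f_m = 0) {
  structure(list(offsets = offsets, arex = values, t1 = t1, f_m = f_m,
                 flag = rep(FALSE, length(offsets))),
            class = "arex_spectrum")
}

# Closed-form ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
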