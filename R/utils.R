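# Internal helpers shared across modules.

# Lorentzian absorption line, L(x) = A * (G/2)^2 / ((G/2)^2 + (x - x0)^2),
# so that L(x0) = A and fwhm = G (in the same units as x).
lorentzian <- function(x, amplitude, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  amplitude * hw2 / (hw2 + (x - center)^2)
}

# Gaussian peak parameterized by height (not area): A * exp(-(x-mu)^2 / (2 sigma^2)).
gaussian_peak <- function(x, amplitude, center, sigma) {
  amplitude * exp(-((x - center)^2) / (2 * sigma^2))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulators never perturb the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of (x, y) restricted to a band, with the band endpoints
# filled in by linear interpolation so the result does not depend on whether
# the band edges fall on grid points.  x may be in either direction.
band_trapz <- function(x, y, band) {
  stopifnot(length(x) == length(y), length(band) == 2L)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  lo <- min(band); hi <- max(band)
  eps <- 1e-9 * max(1, diff(range(x)))
  if (lo < min(x) - eps || hi > max(x) + eps) {
    stop("integration band [", lo, ", ", hi, "] lies outside the sampled range [",
         min(x), ", ", max(x), "]")
  }
  inside <- x > lo & x < hi
  xi <- c(lo, x[inside], hi)
  yi <- c(stats::approx(x, y, xout = lo, rule = 2)$y,
          y[inside],
          stats::approx(x, y, xout = hi, rule = 2)$y)
  pracma::trapz(xi, yi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared Levenberg-Marquardt control: tight tolerances so noiseless
# generate-then-fit round trips recover parameters to numerical precision.
lm_control <- function(maxiter = 400) {
  minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-15, ptol = 1e-15,
                             gtol = 1e-15)
}
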