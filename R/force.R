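#' FSR calibration polynomial
#'
#' The relation between an FSR sensor's conditioned voltage V and the applied
#' force F is modelled as a degree-n polynomial
#' F = p1 V^n + p2 V^(n-1) + ... + pn V + p(n+1), with coefficients ordered
#' highest degree first and 1 <= n <= 9. The default is the identity
#' polynomial (degree 5, F = V), used when synthesising glove data: the
#' study's fitted coefficients were never published, and the identity choice
#' keeps the calibration trivially invertible.
#'
#' @param coeffs Numeric coefficients, highest degree first (length n + 1).
#' @param v_range Valid voltage range, volts.
#' @return An object of class \code{fsr_calibration}.
#' @examples
#' cal <- fsr_calibration()          # F = V
#' fsr_to_force(2.5, cal)            # 2.5 N
#' @export
fsr_calibration <- function(coeffs = c(0, 0, 0, 0, 1, 0), v_range = c(0, 5)) {
  n <- length(coeffs) - 1L
  if (n < 1L || n > 9L) stop("polynomial degree must satisfy 1 <= n <= 9")
  structure(list(coeffs = as.numeric(coeffs), degree = n,
                 v_range = as.numeric(v_range)),
            class = "fsr_calibration")
}

#' Convert FSR voltages to forces
#'
#' Evaluates the calibration polynomial at each voltage (Horner's scheme,
#' coefficients highest degree first). Voltages outside the valid range are
#' clipped with a warning.
#'
#' @param V Numeric vector of voltages.
#' @param calibration An \code{\link{fsr_calibration}}.
#' @return Forces in newtons, same length as \code{V}.
#' @export
fsr_to_force <- function(V, calibration) {
  lo <- calibration$v_range[1]; hi <- calibration$v_range[2]
  if (any(V < lo | V > hi, na.rm = TRUE)) {
    warning("voltages outside [", lo, ", ", hi, "] V clipped")
    V <- pmin(hi, pmax(lo, V))
  }
  out <- rep(0, length(V))
  for (p in calibration$coeffs) out <- out * V + p
  out
}

# invert a monotone calibration by grid interpolation on the valid range;
# exact for the identity default
fsr_invert <- function(force, calibration, grid_n = 2001L) {
  v <- seq(calibration$v_range[1], calibration$v_range[2], length.out = grid_n)
  f <- fsr_to_force(v, calibration)
  if (any(diff(f) < 0)) stop("calibration polynomial is not monotone on its range")
  stats::approx(f, v, xout = force, rule = 2, ties = "ordered")$y
}

#' Fit an FSR calibration polynomial by least squares
#'
#' Fits force = polynomial(voltage) of the requested degree n (1 <= n <= 9)
#' by ordinary least squares on paired (V, F) observations.
#'
#' @param V,F Numeric vectors of voltages and forces (equal length).
#' @param degree Polynomial degree n.
#' @return An \code{\link{fsr_calibration}} with attribute
#'   \code{"residual_rms"}.
#' @export
fit_fsr_polynomial <- function(V, F, degree) {
  if (degree < 1L || degree > 9L) stop("polynomial degree must satisfy 1 <= n <= 9")
  if (length(V) != length(F)) stop("V and F must have equal length")
  if (length(unique(V)) < degree + 1L) {
    stop("need at least degree + 1 distinct voltages")
  }
  X <- outer(V, degree:0, `^`)   # columns: V^n .. V^0, matching p1..p(n+1)
  fit <- stats::lm.fit(X, F)
  if (fit$rank < degree + 1L) stop("rank-deficient design: cannot fit degree ", degree)
  cal <- fsr_calibration(coeffs = unname(fit$coefficients),
                         v_range = range(V))
  attr(cal, "residual_rms") <- sqrt(mean(fit$residuals^2))
  cal
}

#' Grasp-force band geometry
#'
#' Force targets are set at 30% (Low), 60% (Medium) and 90% (High) of the
#' subject's maximum force sum, each widened by +/- 15 percentage points of
#' the maximum. This yields three contiguous, non-overlapping bands on the
#' normalised force axis: Low [0.15, 0.45), Medium [0.45, 0.75),
#' High [0.75, 1].
#'
#' @param max_force_sum Subject maximum force sum (N), > 0.
#' @param thresholds Band centres as fractions of the maximum.
#' @param halfwidth Band half-width in fraction-of-maximum units.
#' @return An object of class \code{force_band_spec}.
#' @export
force_band_spec <- function(max_force_sum,
                            thresholds = c(Low = 0.30, Medium = 0.60, High = 0.90),
                            halfwidth = 0.15) {
  if (max_force_sum <= 0) stop("max_force_sum must be positive")
  structure(list(max_force_sum = max_force_sum,
                 thresholds = thresholds,
                 halfwidth = halfwidth),
            class = "force_band_spec")
}

#' Label a force sum with its band
#'
#' Normalises the force sum by the subject maximum and assigns Low, Medium or
#' High when the fraction falls in [0.15, 0.45), [0.45, 0.75) or [0.75, 1]
#' respectively; fractions below 0.15 are labelled \code{"none"} and
#' fractions above 1 are clipped into High. Band boundaries are lower-closed.
#'
#' @param force_sum Numeric vector of force sums (N), >= 0.
#' @param spec A \code{\link{force_band_spec}}.
#' @return Character vector in \code{c("none", "Low", "Medium", "High")}.
#' @examples
#' band_label(6, force_band_spec(10))  # "Medium" (60% of maximum)
#' @export
band_label <- function(force_sum, spec) {
  if (any(force_sum < 0)) stop("force_sum must be >= 0")
  f <- force_sum / spec$max_force_sum
  lo <- spec$thresholds - spec$halfwidth        # 0.15, 0.45, 0.75
  out <- rep("none", length(f))
  out[f >= lo[["Low"]]] <- "Low"
  out[f >= lo[["Medium"]]] <- "Medium"
  out[f >= lo[["High"]]] <- "High"
  out
}
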