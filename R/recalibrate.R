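# Three-parameter mass recalibration.
#
# Instrument mass error typically vanishes at the lock mass and grows with
# distance from it along the m/z axis.  The correction model is quadratic in
# the experimental m/z:
#
#     m_adjusted = m_e - (a * m_e^2 + b * m_e + c)
#
# fitted by least squares to user-supplied (observed, reference) pairs.
# Because the correction is linear in (a, b, c), ordinary least squares is
# exact and deterministic; a two-stage derivative-free optimizer is provided
# for cross-checking and mirrors optimizers used by instrument software.

#' Fit a quadratic mass-correction model
#'
#' Minimizes the sum of squared residuals `(adjusted(observed_i) -
#' reference_i)^2` over coefficients (a, b, c) of
#' `adjusted(m) = m - (a m^2 + b m + c)`.  With exactly three distinct
#' points the quadratic interpolates and residuals are ~0.  The fit is
#' rejected (with an error) if applying it increases the mean |ppm| error
#' on the calibration points themselves.
#'
#' @param observed Numeric vector of experimental m/z values (>= 3,
#'   distinct), or a 2-column data frame / matrix of (observed, reference).
#' @param reference Numeric vector of matching theoretical m/z values.
#' @param method `"ols"` (exact, default) or `"nelder-mead"` (two-stage
#'   derivative-free minimization restarted from the stage-1 optimum; agrees
#'   with OLS to high precision).
#' @return An object of class `mass_correction` with components
#'   `coefficients` (a, b, c), `points`, `residuals` (reference-scale ppm
#'   per point), `rms_ppm`, and `mean_abs_ppm` before/after.
#' @examples
#' obs <- c(150, 300, 450, 600, 750)
#' ref <- obs - (1e-9 * obs^2 - 2e-6 * obs + 3e-3)
#' fit <- fit_correction(ref + (obs - ref), ref)  # recovers (a, b, c)
#' coef(fit)
#' @export
fit_correction <- function(observed, reference = NULL,
                           method = c("ols", "nelder-mead")) {
  method <- match.arg(method)
  if (is.null(reference)) {
    stopifnot(is.data.frame(observed) || is.matrix(observed),
              ncol(observed) >= 2)
    reference <- as.numeric(observed[[2]])
    observed <- as.numeric(observed[[1]])
  }
  stopifnot(length(observed) == length(reference))
  if (any(observed <= 0) || any(reference <= 0))
    stop("calibration m/z values must be positive")
  if (length(observed) < 3)
    stop("at least 3 calibration points are required")
  if (anyDuplicated(observed))
    stop("duplicate observed m/z values make the fit rank-deficient")

  # deviation = observed - reference = a m^2 + b m + c  (m = observed)
  dev <- observed - reference
  X <- cbind(observed^2, observed, 1)
  if (method == "ols") {
    beta <- stats::lm.fit(X, dev)$coefficients
  } else {
    sse <- function(p) sum((dev - X %*% p)^2)
    s1 <- stats::optim(c(0, 0, 0), sse, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14,
                                      parscale = c(1e-9, 1e-6, 1e-3)))
    s2 <- stats::optim(s1$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-16,
                                      parscale = c(1e-9, 1e-6, 1e-3)))
    beta <- s2$par
  }
  beta <- stats::setNames(as.numeric(beta), c("a", "b", "c"))

  adj <- observed - (beta["a"] * observed^2 + beta["b"] * observed +
                       beta["c"])
  res_ppm <- ppm_error(adj, reference)
  before_ppm <- ppm_error(observed, reference)
  mean_after <- mean(abs(res_ppm))
  mean_before <- mean(abs(before_ppm))
  if (mean_after > mean_before + 1e-12)
    stop("fit rejected: correction increases mean |ppm| on the ",
         "calibration points (", format(mean_before), " -> ",
         format(mean_after), ")")
  structure(list(coefficients = beta,
                 points = data.frame(observed = observed,
                                     reference = reference,
                                     ppm_before = before_ppm,
                                     ppm_after = res_ppm),
                 residuals = res_ppm,
                 rms_ppm = sqrt(mean(res_ppm^2)),
                 mean_abs_ppm = c(before = mean_before, after = mean_after),
                 method = method,
                 call = match.call()),
            class = "mass_correction")
}

#' @export
print.mass_correction <- function(x, digits = 6, ...) {
  cat("Quadratic mass-correction model: m_adj = m - (a*m^2 + b*m + c)\n")
  cat(sprintf("  a = %.6e   b = %.6e   c = %.6e\n",
              x$coefficients["a"], x$coefficients["b"],
              x$coefficients["c"]))
  cat(sprintf("  %d calibration points; RMS residual %.4g ppm; mean |ppm| %.4g -> %.4g\n",
              nrow(x$points), x$rms_ppm, x$mean_abs_ppm["before"],
              x$mean_abs_ppm["after"]))
  invisible(x)
}

#' @export
coef.mass_correction <- function(object, ...) object$coefficients

#' @export
residuals.mass_correction <- function(object, ...) object$residuals

#' @export
fitted.mass_correction <- function(object, ...)
  apply_correction(object, object$points$observed)

#' @export
summary.mass_correction <- function(object, ...) {
  cat(sprintf(
    "Mass correction (%s fit), %d points\n", object$method,
    nrow(object$points)))
  print(object)
  cat("\nPer-point residuals (ppm):\n")
  print(object$points, digits = 6)
  invisible(object)
}

#' Apply a fitted correction to m/z values
#'
#' @param object A `mass_correction`.
#' @param mz Numeric vector of experimental m/z values (or a feature data
#'   frame with an `mz` column, in which case an `adjusted_mz` column is
#'   added).
#' @return Adjusted m/z values (or the augmented data frame).
#' @export
apply_correction <- function(object, mz) {
  stopifnot(inherits(object, "mass_correction"))
  if (is.data.frame(mz)) {
    mz$adjusted_mz <- apply_correction(object, mz$mz)
    return(mz)
  }
  b <- unname(object$coefficients)
  mz - (b[1] * mz^2 + b[2] * mz + b[3])
}

#' @export
predict.mass_correction <- function(object, newdata, ...) {
  apply_correction(object, newdata)
}

#' Summarize mass-error improvement on held-out pairs
#'
#' Compares mean absolute ppm error before and after correction on matched
#' (observed, reference) pairs, excluding the calibration points
#' themselves.
#'
#' @param before Data frame with columns `observed`, `reference` (m/z
#'   pairs before correction).
#' @param after Same pairs with corrected observed m/z (e.g.
#'   `apply_correction(fit, before$observed)` against the same references).
#' @return List with `mean_abs_ppm_before`, `mean_abs_ppm_after`, and
#'   `pct_change` (negative = improvement).
#' @export
delta_ppm_report <- function(before, after) {
  stopifnot(is.data.frame(before), is.data.frame(after),
            nrow(before) == nrow(after))
  if (!nrow(before)) stop("empty pair set")
  b <- mean(abs(ppm_error(before$observed, before$reference)))
  a <- mean(abs(ppm_error(after$observed, after$reference)))
  list(mean_abs_ppm_before = b, mean_abs_ppm_after = a,
       pct_change = if (b > 0) 100 * (a - b) / b else 0)
}

#' Pair features with reference masses for calibration
#'
#' For each reference mass, selects the nearest feature within a coarse ppm
#' window; references with no feature in the window are dropped.
#'
#' @param features Numeric vector of feature m/z, or a feature data frame.
#' @param reference Numeric vector of known reference m/z values.
#' @param tol Pairing window in ppm (default 20).
#' @return Data frame with columns `observed`, `reference`.
#' @export
pair_calibration_points <- function(features, reference, tol = 20) {
  if (is.data.frame(features)) features <- features$mz
  rows <- lapply(reference, function(r) {
    d <- abs(ppm_error(features, r))
    i <- which.min(d)
    if (length(i) && d[i] <= tol)
      data.frame(observed = features[i], reference = r)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(observed = numeric(), reference = numeric())
  else out
}
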