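# Per-voxel signal conditioning: phase unwrapping, phase regression,
# zero-phase temporal filtering, and GLM activation estimates.

#' Temporally unwrap a phase time series
#'
#' Adds integer multiples of 2*pi so that successive differences are bounded
#' by pi. Operates along time; for a matrix input each row (site) is
#' unwrapped independently (synthetic sites carry no spatial phase
#' structure, so no spatial unwrapping is performed).
#'
#' @param ts Numeric vector, or site x time matrix, of wrapped phases in
#'   radians.
#' @return Unwrapped phase, same shape.
#' @export
unwrap_phase <- function(ts) {
  if (is.matrix(ts)) return(t(apply(ts, 1, signal::unwrap)))
  signal::unwrap(ts)
}

#' Phase regression: remove macrovascular signal from magnitude
#'
#' Macrovascular (large-vein and pial) BOLD contributions perturb both the
#' magnitude and the phase of the complex signal, whereas microvascular /
#' tissue signal is magnitude-only. Ordinary least squares of magnitude on
#' the (unwrapped) phase therefore removes the macrovascular component; the
#' residual plus the voxel mean is returned. By construction the output has
#' zero sample correlation with the phase regressor. Intended to run early
#' in the pipeline, before temporal filtering.
#'
#' @param magnitude Numeric vector, or site x time matrix.
#' @param phase Unwrapped phase, same shape.
#' @return Cleaned magnitude, same shape. A constant (zero-variance) phase
#'   regressor leaves the magnitude unchanged with a warning.
#' @export
phase_regress <- function(magnitude, phase) {
  if (is.matrix(magnitude)) {
    stopifnot(all(dim(magnitude) == dim(phase)))
    out <- magnitude
    for (i in seq_len(nrow(magnitude)))
      out[i, ] <- phase_regress(magnitude[i, ], phase[i, ])
    return(out)
  }
  if (length(magnitude) != length(phase))
    stop("magnitude and phase must have equal length")
  if (stats::sd(phase) == 0) {
    warning("constant phase regressor: magnitude returned unchanged")
    return(magnitude)
  }
  fit <- stats::lm.fit(cbind(1, phase), magnitude)
  fit$residuals + mean(magnitude)
}

butter_filtfilt <- function(ts, filt) {
  if (is.matrix(ts)) return(t(apply(ts, 1, butter_filtfilt, filt = filt)))
  signal::filtfilt(filt, ts - mean(ts))  # demeaned; DC removed by design
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (zero phase shift,
#' doubled effective order). The series is demeaned before filtering, so DC
#' is removed exactly. Default band 0.01-0.1 Hz, the standard resting-state
#' fluctuation band.
#'
#' @param ts Numeric vector or site x time matrix.
#' @param low_hz,high_hz Band edges in Hz.
#' @param TR_s Sampling interval in seconds; \code{high_hz} must be below
#'   the Nyquist frequency \code{1/(2 TR_s)}.
#' @return Filtered series, same shape, zero mean.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, TR_s) {
  nyq <- 1 / (2 * TR_s)
  if (high_hz >= nyq)
    stop(sprintf("high edge %g Hz is at or above Nyquist %g Hz for TR = %g s",
                 high_hz, nyq, TR_s))
  if (low_hz <= 0 || low_hz >= high_hz) stop("need 0 < low_hz < high_hz")
  filt <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  butter_filtfilt(ts, filt)
}

#' Zero-phase high-pass filter
#'
#' Order-4 zero-phase Butterworth high-pass (default cutoff 0.01 Hz, the
#' standard drift cutoff for task fMRI). The mean is removed before
#' filtering.
#'
#' @param ts Numeric vector or site x time matrix.
#' @param cutoff_hz Cutoff in Hz; must be below Nyquist.
#' @param TR_s Sampling interval in seconds.
#' @return Filtered series, same shape, zero mean.
#' @export
highpass <- function(ts, cutoff_hz = 0.01, TR_s) {
  nyq <- 1 / (2 * TR_s)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %g Hz is at or above Nyquist %g Hz for TR = %g s",
                 cutoff_hz, nyq, TR_s))
  filt <- signal::butter(4, cutoff_hz / nyq, type = "high")
  butter_filtfilt(ts, filt)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the community-standard parameters
#' (response delay 6, undershoot delay 16, unit dispersions, undershoot
#' ratio 1/6): a positive lobe peaking near 5 s followed by a shallow
#' undershoot near 15 s. The sampled kernel is normalised to peak 1.
#'
#' @param TR_s Sampling interval in seconds (> 0).
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector sampled at \code{t = 0, TR, 2 TR, ...}.
#' @export
double_gamma_hrf <- function(TR_s, duration_s = 32) {
  if (TR_s <= 0) stop("TR_s must be positive")
  t <- seq(0, duration_s, by = TR_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Build a GLM design matrix
#'
#' @param regressors time x k matrix (or vector) of regressors of interest,
#'   e.g. an HRF-convolved task boxcar or a seed time course.
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @return An object of class \code{glm_design}; errors if the design is
#'   rank deficient, naming the collinear columns.
#' @export
glm_design <- function(regressors, add_intercept = TRUE) {
  X <- as.matrix(regressors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(X = X, has_intercept = add_intercept), class = "glm_design")
}

#' Ordinary-least-squares activation estimate
#'
#' Fits \code{ts ~ design} per row, returning for the first regressor of
#' interest (the first non-intercept column, unless \code{term} names
#' another) the effect size, its t statistic with OLS standard error, the
#' normal-quantile z equivalent, and the percent signal change
#' \code{100 * beta * peak-to-peak(regressor) / baseline}, with the baseline
#' taken as the intercept estimate (the voxel baseline mean).
#'
#' @param ts Numeric vector or site x time matrix.
#' @param design A \code{glm_design} (or raw regressor matrix, coerced).
#' @param term Name or index of the regressor of interest.
#' @return data.frame with one row per site: \code{beta},
#'   \code{percent_signal_change}, \code{t_stat}, \code{z_stat}, \code{se},
#'   \code{dof}, \code{baseline}.
#' @export
glm_fit <- function(ts, design, term = NULL) {
  if (!inherits(design, "glm_design")) design <- glm_design(design)
  X <- design$X
  Y <- if (is.matrix(ts)) t(ts) else matrix(ts, ncol = 1)
  if (nrow(Y) != nrow(X)) stop("time series length does not match design")
  if (is.null(term)) term <- if (design$has_intercept) 2L else 1L
  if (is.character(term)) term <- match(term, colnames(X))
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  dof <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[term, term])
  b <- beta[term, ]
  tstat <- ifelse(se > 0, b / se, sign(b) * Inf)
  z <- t_to_z(tstat, dof)
  baseline <- if (design$has_intercept) beta[1, ] else colMeans(Y)
  ptp <- diff(range(X[, term]))
  psc <- 100 * b * ptp / baseline
  data.frame(beta = b, percent_signal_change = psc, t_stat = tstat,
             z_stat = z, se = se, dof = dof, baseline = baseline,
             row.names = NULL)
}

# Signed normal-quantile equivalent of a t statistic (finite-safe).
t_to_z <- function(t_stat, dof) {
  z <- stats::qnorm(stats::pt(abs(t_stat), dof, lower.tail = FALSE,
                              log.p = TRUE), log.p = TRUE,
                    lower.tail = FALSE)
  sign(t_stat) * z
}
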