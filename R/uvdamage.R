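# UV dose bookkeeping and the Poisson zero-event CPD survival analysis.

#' UV dose calibration from exposure/dose reference pairs
#'
#' A UV lamp delivering constant irradiance maps exposure time linearly
#' to dose. The calibration is built from one or more reference pairs
#' (and must be internally consistent to within 1%), e.g. 235 ms for
#' 50 J/m^2.
#'
#' @param exposure_ms Reference exposure times, ms.
#' @param dose_J_m2 Matching doses, J/m^2.
#' @return A `dose_calibration` with the implied irradiance (W/m^2).
#' @export
dose_calibration <- function(exposure_ms, dose_J_m2) {
  if (length(exposure_ms) != length(dose_J_m2) || !length(exposure_ms))
    abort_param("need matching non-empty exposure/dose vectors")
  if (any(exposure_ms <= 0) || any(dose_J_m2 <= 0))
    abort_param("reference pairs must be positive")
  irr <- dose_J_m2 / (exposure_ms / 1000)  # W/m^2
  if ((max(irr) - min(irr)) / mean(irr) > 0.01)
    abort_data(sprintf(
      "inconsistent calibration pairs: implied irradiance spread %.1f%% > 1%%",
      100 * (max(irr) - min(irr)) / mean(irr)))
  structure(list(irradiance_W_m2 = mean(irr),
                 pairs = data.frame(exposure_ms = exposure_ms,
                                    dose_J_m2 = dose_J_m2)),
            class = "dose_calibration")
}

#' Convert between UV dose and exposure time
#'
#' `exposure = dose / irradiance` (linear, exact), and its inverse.
#'
#' @param dose Dose, J/m^2.
#' @param exposure_ms Exposure, ms.
#' @param cal A [dose_calibration()].
#' @return Exposure in ms, or dose in J/m^2.
#' @export
dose_to_exposure <- function(dose, cal) {
  if (any(dose < 0)) abort_param("dose must be >= 0")
  dose / cal$irradiance_W_m2 * 1000
}

#' @rdname dose_to_exposure
#' @export
exposure_to_dose <- function(exposure_ms, cal) {
  if (any(exposure_ms < 0)) abort_param("exposure must be >= 0")
  exposure_ms / 1000 * cal$irradiance_W_m2
}

#' Normalize gel band intensities to an intact-fraction survival curve
#'
#' For each dose, the endonuclease-treated band intensity is divided by
#' its untreated counterpart (the split-sample relative quantification).
#' Ratios slightly above 1 are clipped to 1; ratios above 1.02 raise a
#' warning.
#'
#' @param raw `data.frame` with columns `dose_J_m2`, `treated`,
#'   `untreated` (and optionally `replicate`).
#' @return `data.frame` of class `survival_curve`: `dose_J_m2`,
#'   `intact_fraction` plus the input intensity columns.
#' @export
normalize_bands <- function(raw) {
  need <- c("dose_J_m2", "treated", "untreated")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_format(sprintf("band table missing columns: %s",
                         paste(miss, collapse = ", ")))
  bad <- which(raw$untreated <= 0)
  if (length(bad))
    abort_data(sprintf("untreated intensity <= 0 at dose %g J/m^2",
                       raw$dose_J_m2[bad[1]]))
  frac <- raw$treated / raw$untreated
  if (any(frac > 1.02))
    warning(sprintf("%d intact fraction(s) > 1.02 clipped to 1",
                    sum(frac > 1.02)))
  out <- raw
  out$intact_fraction <- pmin(frac, 1)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fit the exponential CPD survival decay constant
#'
#' Nonlinear least squares of `I0 * exp(-K * dose)` against the intact
#' fraction on the linear intensity scale, with `K >= 0` enforced. By
#' default the amplitude is fixed at `I0 = 1` since intact fractions
#' are self-normalized per dose; `fix_I0 = FALSE` frees the amplitude
#' as a sensitivity check, and `log_scale = TRUE` fits
#' `log(intact) = log(I0) - K * dose` by ordinary least squares
#' instead.
#'
#' @param curve A `survival_curve` (or any `data.frame` with
#'   `dose_J_m2` and `intact_fraction`).
#' @param fix_I0 Fix the amplitude at 1 (default `TRUE`).
#' @param log_scale Fit on the log scale (default `FALSE`).
#' @return A `decay_fit` object: `K` (m^2/J), `I0`, `rss`, `method`,
#'   and `constant_flag` (set when the data show no decay and K = 0 is
#'   returned).
#' @export
fit_decay <- function(curve, fix_I0 = TRUE, log_scale = FALSE) {
  need <- c("dose_J_m2", "intact_fraction")
  miss <- setdiff(need, names(curve))
  if (length(miss))
    abort_format(sprintf("survival curve missing columns: %s",
                         paste(miss, collapse = ", ")))
  d <- curve$dose_J_m2; y <- curve$intact_fraction
  if (length(unique(d)) < 3) abort_input("need at least 3 distinct doses")
  if (any(y <= 0)) abort_data("intact_fraction must be > 0 for fitting")
  constant_flag <- FALSE
  if (stats::sd(y) == 0 && any(d > 0)) {
    # no decay signal: K = 0 with flag, not an error
    K <- 0; I0 <- if (fix_I0) 1 else y[1]
    constant_flag <- TRUE
    rss <- sum((y - I0)^2)
    method <- "constant"
  } else if (log_scale) {
    if (fix_I0) {
      # no intercept: minimize sum (log y + K d)^2
      K <- max(0, -sum(d * log(y)) / sum(d^2))
      I0 <- 1
    } else {
      fit <- stats::lm(log(y) ~ d)
      K <- max(0, -unname(stats::coef(fit)[2]))
      I0 <- exp(unname(stats::coef(fit)[1]))
    }
    rss <- sum((y - I0 * exp(-K * d))^2)
    method <- "log-ols"
  } else {
    k0 <- {
      pos <- d > 0
      if (any(pos)) max(1e-8, stats::median(-log(y[pos]) / d[pos])) else 1e-4
    }
    if (fix_I0) {
      fit <- minpack.lm::nlsLM(y ~ exp(-K * d), start = list(K = k0),
                               lower = c(K = 0))
      K <- unname(stats::coef(fit)["K"]); I0 <- 1
    } else {
      fit <- minpack.lm::nlsLM(y ~ I0 * exp(-K * d),
                               start = list(I0 = max(y), K = k0),
                               lower = c(I0 = 0, K = 0))
      K <- unname(stats::coef(fit)["K"])
      I0 <- unname(stats::coef(fit)["I0"])
    }
    rss <- sum(stats::resid(fit)^2)
    method <- "nls-linear"
    if (K == 0) constant_flag <- stats::sd(y) == 0
  }
  structure(list(K = K, I0 = I0, rss = rss, method = method,
                 constant_flag = constant_flag,
                 data = data.frame(dose_J_m2 = d, intact_fraction = y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Exponential CPD survival fit (Poisson zero-event model)\n")
  cat(sprintf("  K = %.4g m^2/J, I0 = %.4g  [%s]\n", x$K, x$I0, x$method))
  cat(sprintf("  RSS = %.3g over %d points\n", x$rss, nrow(x$data)))
  if (x$constant_flag) cat("  note: no decay detected (K = 0 flagged)\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(K = object$K, I0 = object$I0)

#' Predicted intact fraction of a decay fit
#' @param object A `decay_fit`.
#' @param newdata Optional `data.frame` with `dose_J_m2`.
#' @param ... Unused.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose_J_m2 else newdata$dose_J_m2
  object$I0 * exp(-object$K * d)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$intact_fraction - predict(object)
}

#' Plot a survival curve and its exponential fit
#' @param x A `decay_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$dose_J_m2, x$data$intact_fraction,
                 xlab = "UV dose (J/m^2)", ylab = "intact fraction", ...)
  dd <- seq(0, max(x$data$dose_J_m2), length.out = 200)
  graphics::lines(dd, x$I0 * exp(-x$K * dd), col = "red")
  invisible(x)
}

#' Poisson zero-event survival model
#'
#' Lesions accrue independently with mean `K * dose`; the probability
#' of an intact molecule (zero lesions) is `exp(-K * dose)`. Doubling
#' the dose doubles the expected lesion count exactly.
#'
#' @param K Decay constant, m^2/J.
#' @param dose Dose, J/m^2.
#' @return Intact probability, or expected lesion count.
#' @export
poisson_zero_event <- function(K, dose) {
  if (any(K < 0) || any(dose < 0)) abort_param("K and dose must be >= 0")
  exp(-K * dose)
}

#' @rdname poisson_zero_event
#' @export
lesion_mean <- function(K, dose) {
  if (any(K < 0) || any(dose < 0)) abort_param("K and dose must be >= 0")
  K * dose
}
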