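# Plate-reader kinetics: blanking, F/OD normalization, growth phases,
# doubling times, steady-state fluorescence.

#' Blank a plate-reader run and normalize fluorescence to cell density
#'
#' OD values are corrected by the mean of the medium-blank wells at each
#' time point; fluorescence by the mean of the negative-control wells
#' (autofluorescence). F/OD is reported only where the corrected OD
#' exceeds `od_floor`, since the ratio diverges at vanishing density.
#' Missing blank values at a time point are linearly interpolated from
#' neighbouring time points with a warning.
#'
#' @param raw Long `data.frame`: `time_h`, `well`, `od600`, `fluor`.
#' @param od_blank Well IDs of medium blanks.
#' @param fluor_blank Well IDs of the negative-control (autofluorescence)
#'   wells.
#' @param od_floor Minimum corrected OD for F/OD (default 0.02).
#' @return List with `growth` (`time_h`, `well`, `od600` corrected,
#'   `below_zero` flag) and `fluorescence` (`time_h`, `well`, `fluor`
#'   corrected, `fluor_per_od`).
#' @export
blank_and_normalize <- function(raw, od_blank, fluor_blank,
                                od_floor = 0.02) {
  need <- c("time_h", "well", "od600", "fluor")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort_format(sprintf("plate table missing columns: %s",
                         paste(miss, collapse = ", ")))
  times <- sort(unique(raw$time_h))
  blank_mean <- function(wells, col) {
    sub <- raw[raw$well %in% wells, ]
    if (!nrow(sub)) abort_input("no blank wells present in the table")
    m <- tapply(sub[[col]], sub$time_h, mean, na.rm = TRUE)
    v <- as.numeric(m[as.character(times)])
    if (any(is.na(v))) {
      if (all(is.na(v))) abort_input("blank wells contain no usable values")
      warning("missing blank values interpolated from neighbouring times")
      v <- stats::approx(times[!is.na(v)], v[!is.na(v)], xout = times,
                         rule = 2)$y
    }
    v
  }
  odb <- blank_mean(od_blank, "od600")
  flb <- blank_mean(fluor_blank, "fluor")
  sample_rows <- !(raw$well %in% union(od_blank, fluor_blank))
  s <- raw[sample_rows, , drop = FALSE]
  ti <- match(s$time_h, times)
  od_corr <- s$od600 - odb[ti]
  f_corr <- s$fluor - flb[ti]
  growth <- data.frame(time_h = s$time_h, well = s$well, od600 = od_corr,
                       below_zero = od_corr <= 0)
  fl <- data.frame(time_h = s$time_h, well = s$well, fluor = f_corr,
                   fluor_per_od = ifelse(od_corr > od_floor,
                                         f_corr / od_corr, NA_real_))
  list(growth = growth, fluorescence = fl)
}

# rolling-window slope of log(OD) by local least squares
rolling_log_slope <- function(t, od, window) {
  n <- length(t)
  half <- floor(window / 2)
  slope <- rep(NA_real_, n)
  ly <- ifelse(od > 0, log(od), NA_real_)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tt <- t[lo:hi]; yy <- ly[lo:hi]
    ok <- is.finite(yy)
    if (sum(ok) >= 2)
      slope[i] <- stats::cov(tt[ok], yy[ok]) / stats::var(tt[ok])
  }
  slope
}

#' Segment a growth curve into lag, exponential and stationary phases
#'
#' The log-OD slope is computed in a rolling window; the exponential
#' phase is the maximal contiguous region where the slope reaches at
#' least `frac` of its maximum, lag is everything before and stationary
#' everything after. A curve whose maximal slope is not positive is
#' labelled all-lag with `no_growth = TRUE`.
#'
#' @param time Time, h.
#' @param od Blank-corrected OD600 (same length).
#' @param window Rolling window size in points (default 5).
#' @param frac Fraction of the maximal slope defining the exponential
#'   region (default 0.8).
#' @return List: `labels` (factor lag/exponential/stationary per point),
#'   `exp_start`, `exp_end` (times), `max_slope` (1/h), `no_growth`.
#' @export
segment_phases <- function(time, od, window = 5, frac = 0.8) {
  if (length(time) < 10) abort_input("need at least 10 time points")
  if (any(diff(time) <= 0)) abort_param("time must be strictly increasing")
  slope <- rolling_log_slope(time, od, window)
  ms <- suppressWarnings(max(slope, na.rm = TRUE))
  n <- length(time)
  if (!is.finite(ms) || ms <= 0) {
    return(list(labels = factor(rep("lag", n),
                                levels = c("lag", "exponential", "stationary")),
                exp_start = NA_real_, exp_end = NA_real_,
                max_slope = ms, no_growth = TRUE, slope = slope))
  }
  hot <- !is.na(slope) & slope >= frac * ms
  # maximal contiguous run containing the slope maximum
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  imax <- which.max(slope)
  run_id <- which(starts <= imax & ends >= imax & runs$values)
  if (!length(run_id)) run_id <- which(runs$values)[which.max(
    runs$lengths[runs$values])]
  i1 <- starts[run_id]; i2 <- ends[run_id]
  lab <- rep("stationary", n)
  lab[seq_len(n) < i1] <- "lag"
  lab[seq(i1, i2)] <- "exponential"
  list(labels = factor(lab, levels = c("lag", "exponential", "stationary")),
       exp_start = time[i1], exp_end = time[i2], max_slope = ms,
       no_growth = FALSE, slope = slope)
}

#' Doubling time from the exponential window
#'
#' Least-squares slope m of `ln(OD)` versus time over the exponential
#' window; the doubling time is `ln(2)/m`. Invariant under scaling OD
#' by any positive constant.
#'
#' @param time Time, h.
#' @param od OD600 (> 0 inside the window).
#' @param window Logical or integer index vector selecting the
#'   exponential points; default: the exponential phase found by
#'   [segment_phases()].
#' @return Doubling time, h.
#' @export
doubling_time <- function(time, od, window = NULL) {
  if (is.null(window))
    window <- segment_phases(time, od)$labels == "exponential"
  t <- time[window]; y <- od[window]
  if (length(t) < 4) abort_input("exponential window needs >= 4 points")
  if (any(y <= 0)) abort_data("OD must be positive inside the window")
  m <- unname(stats::coef(stats::lm(log(y) ~ t))[2])
  if (m <= 0) abort_data("non-positive growth slope; doubling time undefined")
  log(2) / m
}

#' Steady-state fluorescence per OD over a window
#'
#' Mean and standard deviation of F/OD across the selected (exponential
#' phase) window. In balanced growth this plateau equals
#' `r_FP / (mu + r_De)`.
#'
#' @param fluor_per_od F/OD series.
#' @param window Logical or integer index vector.
#' @return List with `mean` and `sd`.
#' @export
steady_state_fluorescence <- function(fluor_per_od, window) {
  v <- fluor_per_od[window]
  v <- v[is.finite(v)]
  if (!length(v)) abort_input("steady-state window is empty")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Phosphate standard curve and unknown quantification
#'
#' Ordinary least squares `A820 = a * nmol + b` through the standards;
#' unknown absorbances invert to `(A - b)/a`. Estimates outside the
#' standard range are flagged as extrapolated.
#'
#' @param standards `data.frame` with `nmol` and `A820` (>= 3 rows
#'   spanning the unknowns).
#' @param unknowns A820 values to quantify.
#' @return List: `estimates` (`data.frame` `A820`, `nmol`,
#'   `extrapolated`), `slope`, `intercept`, `r_squared`.
#' @export
phosphate_standard <- function(standards, unknowns) {
  if (!all(c("nmol", "A820") %in% names(standards)))
    abort_format("standards need columns 'nmol' and 'A820'")
  if (nrow(standards) < 3) abort_input("need at least 3 standards")
  fit <- stats::lm(A820 ~ nmol, data = standards)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (a <= 0) abort_data("calibration slope must be positive")
  est <- (unknowns - b) / a
  rng <- range(standards$nmol)
  tss <- sum((standards$A820 - mean(standards$A820))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(estimates = data.frame(A820 = unknowns, nmol = est,
                              extrapolated = est < rng[1] | est > rng[2]),
       slope = a, intercept = b, r_squared = r2)
}

#' Langmuir monolayer compressibility modulus
#'
#' `k = -A * (dpi/dA)` at constant temperature, computed by central
#' finite differences on the (optionally moving-average smoothed)
#' isotherm, one-sided at the endpoints.
#'
#' @param isotherm `data.frame` with `area_A2` and `pressure_mN_m`
#'   (>= 5 points on the compression branch).
#' @param smooth_window Odd moving-average window applied to the
#'   pressure before differentiation; 1 disables smoothing (default 1).
#' @return `data.frame`: `area_A2`, `pressure_mN_m`, `k_mN_m`, ordered
#'   by decreasing area.
#' @export
compressibility_modulus <- function(isotherm, smooth_window = 1) {
  if (!all(c("area_A2", "pressure_mN_m") %in% names(isotherm)))
    abort_format("isotherm needs columns 'area_A2' and 'pressure_mN_m'")
  df <- isotherm[order(-isotherm$area_A2), , drop = FALSE]
  df <- df[!duplicated(df$area_A2), , drop = FALSE]
  if (nrow(df) < 5) abort_input("need at least 5 distinct isotherm points")
  if (any(diff(df$area_A2) >= 0))
    abort_data("molecular area not strictly monotone after deduplication")
  A <- df$area_A2
  p <- df$pressure_mN_m
  if (smooth_window > 1) {
    k <- floor(smooth_window / 2)
    ps <- p
    for (i in seq_along(p)) {
      lo <- max(1, i - k); hi <- min(length(p), i + k)
      ps[i] <- mean(p[lo:hi])
    }
    p <- ps
  }
  n <- length(A)
  dpda <- numeric(n)
  dpda[1] <- (p[2] - p[1]) / (A[2] - A[1])
  dpda[n] <- (p[n] - p[n - 1]) / (A[n] - A[n - 1])
  if (n > 2)
    dpda[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (A[3:n] - A[1:(n - 2)])
  data.frame(area_A2 = A, pressure_mN_m = df$pressure_mN_m,
             k_mN_m = -A * dpda)
}

#' FTIR spectrum preprocessing: normalization, second derivative, peaks
#'
#' The spectrum is normalized to its local maximum within
#' `ref_halfwidth` of the reference band (default: the asymmetric CH2
#' stretch at 2925 1/cm), the second derivative is computed with a
#' Savitzky-Golay differentiator, and peaks are reported as local
#' minima of the second derivative deeper than `min_depth` times the
#' deepest minimum.
#'
#' @param spectrum `data.frame` with `wavenumber_cm` (monotone grid)
#'   and `absorbance`.
#' @param ref_peak Reference band position, 1/cm (default 2925).
#' @param ref_halfwidth Search half-width around the reference, 1/cm
#'   (default 20).
#' @param window Savitzky-Golay window length, points (odd, default 11).
#' @param order Savitzky-Golay polynomial order (default 3).
#' @param min_depth Relative prominence threshold in (0, 1] (default
#'   0.1).
#' @return List: `spectrum` (`wavenumber_cm`, `normalized`,
#'   `second_deriv`) and `peaks` (`wavenumber_cm`, `depth`).
#' @export
ftir_preprocess <- function(spectrum, ref_peak = 2925, ref_halfwidth = 20,
                            window = 11, order = 3, min_depth = 0.1) {
  if (!all(c("wavenumber_cm", "absorbance") %in% names(spectrum)))
    abort_format("spectrum needs columns 'wavenumber_cm' and 'absorbance'")
  wn <- spectrum$wavenumber_cm
  ab <- spectrum$absorbance
  if (any(diff(wn) <= 0) && any(diff(wn) >= 0))
    abort_param("wavenumber grid must be monotone")
  if (wn[1] > wn[length(wn)]) { wn <- rev(wn); ab <- rev(ab) }
  if (ref_peak < min(wn) || ref_peak > max(wn))
    abort_param("reference peak outside the spectral range")
  near <- abs(wn - ref_peak) <= ref_halfwidth
  ref_val <- max(ab[near])
  if (ref_val == 0) abort_data("zero absorbance at the reference band")
  norm <- ab / ref_val
  step <- mean(diff(wn))
  d2 <- signal::sgolayfilt(norm, p = order, n = window, m = 2) / step^2
  n <- length(d2)
  is_min <- c(FALSE, d2[2:(n - 1)] < d2[1:(n - 2)] &
                d2[2:(n - 1)] < d2[3:n], FALSE)
  depth <- -d2
  thr <- min_depth * max(depth)
  sel <- is_min & depth >= thr & depth > 0
  list(spectrum = data.frame(wavenumber_cm = wn, normalized = norm,
                             second_deriv = d2),
       peaks = data.frame(wavenumber_cm = wn[sel], depth = depth[sel]))
}
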