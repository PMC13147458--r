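# Subsampled, sample-size-normalized Mann-Whitney U comparison of
# weighted mean-jump-distance datasets -- the package's core statistic.

#' Weighted Mann-Whitney U statistic
#'
#' Computes the U statistics of two samples with positive integer
#' frequency weights (expanded as multiplicities). Ties receive half a
#' win (midrank-equivalent): `U_a = sum over pairs of 1(a > b) +
#' 0.5 * 1(a == b)`, so `U_a + U_b = n_a * n_b`.
#'
#' The two-sided p-value uses the exact null distribution of U
#' ([stats::pwilcox]) when there are no ties and `n_a * n_b <= 400`,
#' otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric samples (non-empty).
#' @param w_a,w_b Positive integer frequency weights (default all 1).
#' @return List with `U_a`, `U_b`, `p_value`, `n_a`, `n_b` (expanded
#'   sizes).
#' @export
mann_whitney_u <- function(a, b, w_a = NULL, w_b = NULL) {
  if (!length(a) || !length(b)) abort_input("both samples must be non-empty")
  w_a <- w_a %||% rep(1L, length(a))
  w_b <- w_b %||% rep(1L, length(b))
  if (any(w_a < 1) || any(w_b < 1) ||
      any(w_a != round(w_a)) || any(w_b != round(w_b)))
    abort_input("weights must be positive integers")
  ae <- rep(a, times = w_a)
  be <- rep(b, times = w_b)
  n_a <- length(ae); n_b <- length(be)
  r <- rank(c(ae, be))
  U_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  U_b <- n_a * n_b - U_a
  ties <- table(c(ae, be))
  has_ties <- any(ties > 1)
  if (!has_ties && n_a * n_b <= 400) {
    p <- if (U_a > n_a * n_b / 2)
      stats::pwilcox(U_a - 1, n_a, n_b, lower.tail = FALSE)
    else stats::pwilcox(U_a, n_a, n_b)
    p <- min(1, 2 * p)
  } else {
    N <- n_a + n_b
    mu <- n_a * n_b / 2
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- U_a - mu
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U_a = U_a, U_b = U_b, p_value = p, n_a = n_a, n_b = n_b)
}

#' Normalize a Mann-Whitney U to the sample sizes
#'
#' Folded normalization `u = min(U_a, U_b) / (n_a * n_b)`, mapping to
#' `[0, 0.5]`: 0.5 means the groups are indistinguishable (U_a = U_b),
#' 0 means complete separation.
#'
#' @param U_a,U_b The two U statistics (must sum to `n_a * n_b`).
#' @param n_a,n_b Group sizes.
#' @return Normalized u in `[0, 0.5]`.
#' @export
normalize_u <- function(U_a, U_b, n_a, n_b) {
  if (abs(U_a + U_b - n_a * n_b) > 1e-8 * max(1, n_a * n_b))
    stop_halospt("U_a + U_b must equal n_a * n_b", "halospt_internal_error")
  min(U_a, U_b) / (n_a * n_b)
}

#' Configuration for the subsampled U comparison
#'
#' @param removal_fraction Fraction of entries removed from each group
#'   per replicate (default 0.40).
#' @param n_replicates Number of subsampling replicates (default 1000).
#' @param seed RNG seed or `NULL`.
#' @param truncation_threshold Fraction of replicate mass in the
#'   histogram bin touching 0.5 above which the distribution is treated
#'   as truncated and summarized by a Gaussian fit (default 0.10).
#' @param n_bins Histogram bins over `[0, 0.5]` (default 50).
#' @return A `u_comparison_config` list.
#' @export
u_comparison_config <- function(removal_fraction = 0.40,
                                n_replicates = 1000, seed = NULL,
                                truncation_threshold = 0.10, n_bins = 50) {
  check_number(removal_fraction, "removal_fraction", lower = 0, upper = 1,
               allow_equal = FALSE)
  check_number(n_replicates, "n_replicates", lower = 2)
  check_number(truncation_threshold, "truncation_threshold", lower = 0,
               upper = 1)
  check_number(n_bins, "n_bins", lower = 2)
  structure(list(removal_fraction = removal_fraction,
                 n_replicates = as.integer(n_replicates), seed = seed,
                 truncation_threshold = truncation_threshold,
                 n_bins = as.integer(n_bins)),
            class = "u_comparison_config")
}

# entries retained per group and replicate: floor((1 - removal) * n)
kept_count <- function(n, removal_fraction) {
  max(1L, as.integer(floor((1 - removal_fraction) * n + 1e-7)))
}

# least-squares Gaussian fit to a histogram of replicate u values;
# returns c(mu, sigma) or NULL on failure
fit_gaussian_hist <- function(u, n_bins) {
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  counts <- graphics::hist(u, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (stats::sd(u) == 0) return(c(mu = u[1], sigma = 0))
  start <- list(amp = max(counts), mu = sum(centers * counts) / sum(counts),
                sigma = max(stats::sd(u), diff(breaks)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ amp * exp(-(centers - mu)^2 / (2 * sigma^2)),
                      start = start,
                      lower = c(amp = 0, mu = -1, sigma = 1e-6),
                      upper = c(amp = Inf, mu = 2, sigma = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(mu = mean(u), sigma = stats::sd(u)))
  cf <- stats::coef(fit)
  c(mu = unname(cf["mu"]), sigma = abs(unname(cf["sigma"])))
}

# core replicate loop; assumes RNG state already seeded by the caller
subsample_u_replicates <- function(data_a, data_b, config) {
  n_a <- nrow(data_a); n_b <- nrow(data_b)
  keep_a <- kept_count(n_a, config$removal_fraction)
  keep_b <- kept_count(n_b, config$removal_fraction)
  u <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    ia <- sample.int(n_a, keep_a)
    ib <- sample.int(n_b, keep_b)
    mw <- mann_whitney_u(data_a$mjd_nm[ia], data_b$mjd_nm[ib],
                         data_a$weight[ia], data_b$weight[ib])
    u[r] <- normalize_u(mw$U_a, mw$U_b, mw$n_a, mw$n_b)
  }
  u
}

summarize_u <- function(u, config, n_a, n_b, n_entries_a, n_entries_b,
                        label = NULL) {
  breaks <- seq(0, 0.5, length.out = config$n_bins + 1)
  top_mass <- mean(u >= breaks[length(breaks) - 1])
  truncated <- top_mass >= config$truncation_threshold
  gaussian_mu <- gaussian_sigma <- NA_real_
  if (truncated) {
    g <- fit_gaussian_hist(u, config$n_bins)
    gaussian_mu <- g[["mu"]]; gaussian_sigma <- g[["sigma"]]
    mean_u <- gaussian_mu
    median_u <- gaussian_mu
    ci5 <- min(max(gaussian_mu - 1.645 * gaussian_sigma, 0), 0.5)
    ci95 <- min(max(gaussian_mu + 1.645 * gaussian_sigma, 0), 0.5)
  } else {
    mean_u <- mean(u)
    median_u <- stats::median(u)
    ci5 <- unname(stats::quantile(u, 0.05))
    ci95 <- unname(stats::quantile(u, 0.95))
  }
  structure(list(u = u, mean = mean_u, median = median_u,
                 ci5 = ci5, ci95 = ci95, truncated = truncated,
                 gaussian_mu = gaussian_mu, gaussian_sigma = gaussian_sigma,
                 n_a = n_a, n_b = n_b,
                 n_entries_a = n_entries_a, n_entries_b = n_entries_b,
                 config = config, label = label),
            class = "u_summary")
}

#' Subsampled normalized-U comparison of two wMJD datasets
#'
#' The central comparison procedure: in each of `n_replicates`
#' replicates each group is subsampled without replacement down to
#' `floor((1 - removal_fraction) * n)` entries (tracks), the
#' weighted Mann-Whitney U of the remaining entries is computed, and
#' the folded normalized u = min(U_a, U_b)/(n_a n_b) is recorded. The
#' replicate distribution is summarized by mean, median and 5%/95%
#' quantiles; when the distribution is truncated at 0.5 (at least
#' `truncation_threshold` of the mass in the bin touching 0.5) a
#' Gaussian is least-squares fitted to the binned frequencies and the
#' summary statistics are taken from the fitted curve
#' (`ci = mu +- 1.645 sigma`, clipped to `[0, 0.5]`).
#'
#' @param data_a,data_b `wmjd` datasets (columns `mjd_nm`, `weight`),
#'   each with at least 5 entries.
#' @param config A [u_comparison_config()].
#' @return A `u_summary` object.
#' @export
subsample_compare <- function(data_a, data_b,
                              config = u_comparison_config()) {
  if (nrow(data_a) < 5 || nrow(data_b) < 5)
    abort_input("each group needs at least 5 wMJD entries")
  u <- with_seed(config$seed,
                 subsample_u_replicates(data_a, data_b, config))
  s <- summarize_u(u, config,
                   n_a = sum(data_a$weight), n_b = sum(data_b$weight),
                   n_entries_a = nrow(data_a), n_entries_b = nrow(data_b),
                   label = paste(data_a$condition[1], "vs",
                                 data_b$condition[1]))
  s$n_kept_a <- kept_count(nrow(data_a), config$removal_fraction)
  s$n_kept_b <- kept_count(nrow(data_b), config$removal_fraction)
  s
}

#' Control split: empirical null of the subsampled U comparison
#'
#' Randomly halves one wMJD dataset (entry-level; the larger half gets
#' the extra entry when n is odd) and runs [subsample_compare()] on the
#' halves. With well-mixed data the summary mean is close to 0.5.
#'
#' @param data A `wmjd` dataset with at least 10 entries.
#' @param config A [u_comparison_config()]; its `seed` governs both the
#'   split and the subsampling.
#' @return A `u_summary` object.
#' @export
control_split <- function(data, config = u_comparison_config()) {
  n <- nrow(data)
  if (n < 10) abort_input("control split needs at least 10 entries")
  with_seed(config$seed, {
    idx <- sample.int(n)
    n_half <- ceiling(n / 2)
    a <- data[idx[seq_len(n_half)], , drop = FALSE]
    b <- data[idx[(n_half + 1):n], , drop = FALSE]
    cfg2 <- config
    cfg2$seed <- NULL  # inherit the RNG stream of this block
    u <- subsample_u_replicates(a, b, cfg2)
    s <- summarize_u(u, config, n_a = sum(a$weight), n_b = sum(b$weight),
                     n_entries_a = nrow(a), n_entries_b = nrow(b),
                     label = paste0("control split of ", data$condition[1]))
    s$n_kept_a <- kept_count(nrow(a), config$removal_fraction)
    s$n_kept_b <- kept_count(nrow(b), config$removal_fraction)
    s
  })
}

#' Tabulate normalized-U summaries across conditions
#'
#' @param summaries List of entries, each a list with elements `dose`
#'   (J/m^2), `recovery` (min) and `summary` (a `u_summary`).
#' @return Long `data.frame`: `dose`, `recovery_min`, `u_mean`, `u_ci5`,
#'   `u_ci95`, `truncated` -- a machine-readable dose-response table.
#' @export
dose_response_table <- function(summaries) {
  if (!length(summaries)) abort_input("no summaries supplied")
  do.call(rbind, lapply(summaries, function(e) {
    s <- e$summary
    data.frame(dose = e$dose, recovery_min = e$recovery,
               u_mean = s$mean, u_ci5 = s$ci5, u_ci95 = s$ci95,
               truncated = s$truncated)
  }))
}

#' @export
print.u_summary <- function(x, ...) {
  cat("Subsampled normalized Mann-Whitney U comparison\n")
  if (!is.null(x$label)) cat("  ", x$label, "\n", sep = "")
  cat(sprintf("  entries: %d vs %d (expanded sizes %d vs %d)\n",
              x$n_entries_a, x$n_entries_b, x$n_a, x$n_b))
  cat(sprintf("  replicates: %d, removal fraction: %.2f\n",
              x$config$n_replicates, x$config$removal_fraction))
  cat(sprintf("  mean u = %.4f, median = %.4f, 5%%-95%% CI [%.4f, %.4f]\n",
              x$mean, x$median, x$ci5, x$ci95))
  if (x$truncated)
    cat(sprintf(
      "  distribution truncated at 0.5; Gaussian fit mu = %.4f, sigma = %.4f\n",
      x$gaussian_mu, x$gaussian_sigma))
  invisible(x)
}

#' @export
summary.u_summary <- function(object, ...) {
  data.frame(mean = object$mean, median = object$median,
             ci5 = object$ci5, ci95 = object$ci95,
             truncated = object$truncated,
             gaussian_mu = object$gaussian_mu,
             gaussian_sigma = object$gaussian_sigma,
             n_a = object$n_a, n_b = object$n_b)
}

#' Histogram of the replicate normalized-U distribution
#' @param x A `u_summary`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.u_summary <- function(x, ...) {
  breaks <- seq(0, 0.5, length.out = x$config$n_bins + 1)
  graphics::hist(x$u, breaks = breaks,
                 xlab = "normalized U", main = x$label %||% "u replicates",
                 ...)
  graphics::abline(v = x$mean, col = "red", lwd = 2)
  if (x$truncated && is.finite(x$gaussian_mu)) {
    centers <- seq(0, 0.5, length.out = 200)
    counts <- graphics::hist(x$u, breaks = breaks, plot = FALSE)$counts
    amp <- max(counts)
    graphics::lines(centers,
                    amp * exp(-(centers - x$gaussian_mu)^2 /
                                (2 * x$gaussian_sigma^2)), col = "blue")
  }
  invisible(x)
}
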