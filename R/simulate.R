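# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the downstream analyses assume.

# Run expr with a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

rlnorm_cv <- function(n, cv) {
  # multiplicative log-normal noise with unit mean and coefficient of
  # variation cv; positivity-preserving
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default UV-dose / recovery-time mobility response
#'
#' Maps an applied UV dose (J/m^2) and post-exposure recovery time (min)
#' to the stationary occupancy of the slow diffusive state. A logistic
#' curve in dose, scaled linearly by recovery time up to a reference
#' recovery, raises the occupancy from `p_base` (untreated) towards
#' `p_max` (maximal damage response). Monotone non-decreasing in both
#' arguments; any user-supplied monotone function with the same
#' signature can replace it in [track_sim_config()].
#'
#' @param p_base Slow-state occupancy without damage (default 0.3).
#' @param p_max Occupancy at saturating dose and recovery (default 0.6).
#' @param dose_half Dose of half-maximal logistic response, J/m^2.
#' @param dose_scale Logistic width, J/m^2.
#' @param recovery_ref Recovery time (min) at which the response is
#'   fully developed.
#' @return A function `(dose, recovery) -> occupancy in [0, 1]`.
#' @export
mobility_response <- function(p_base = 0.3, p_max = 0.6, dose_half = 75,
                              dose_scale = 25, recovery_ref = 180) {
  force(p_base); force(p_max); force(dose_half); force(dose_scale)
  force(recovery_ref)
  function(dose, recovery) {
    eff <- stats::plogis((dose - dose_half) / dose_scale) -
      stats::plogis(-dose_half / dose_scale)
    eff <- pmax(eff, 0) * pmin(recovery / recovery_ref, 1)
    pmin(pmax(p_base + (p_max - p_base) * eff, 0), 1)
  }
}

#' Configuration for the two-state diffusion track simulator
#'
#' Emitters diffuse inside cell-shaped regions, switching between a slow
#' (DNA-bound-like) and a fast (scanning) state; positions are observed
#' with Gaussian localization noise and tracks terminate geometrically
#' (photobleaching / blinking-off). Defaults follow a 20 ms sptPALM
#' acquisition of a transiently DNA-binding protein.
#'
#' @param frame_interval Frame time, s (default 0.02).
#' @param n_frames Frames in the acquisition (default 10000).
#' @param D_slow,D_fast Diffusion coefficients of the two states,
#'   um^2/s (defaults 0.02 and 0.3).
#' @param p_slow Function `(dose, recovery) -> slow-state occupancy`,
#'   default [mobility_response()].
#' @param switch_prob Per-frame state-switch propensity in \[0, 1\]
#'   (default 0.1).
#' @param sigma_loc Localization precision, nm (default 30).
#' @param mean_track_len Mean track length in localizations (geometric
#'   survival; default 8).
#' @param emitters_per_cell Emitters simulated per cell (default 50).
#' @param seed Integer RNG seed or `NULL`.
#' @return A `track_sim_config` list.
#' @export
track_sim_config <- function(frame_interval = 0.02, n_frames = 10000,
                             D_slow = 0.02, D_fast = 0.3,
                             p_slow = mobility_response(),
                             switch_prob = 0.1, sigma_loc = 30,
                             mean_track_len = 8, emitters_per_cell = 50,
                             seed = NULL) {
  check_number(frame_interval, "frame_interval", lower = 0, allow_equal = FALSE)
  check_number(n_frames, "n_frames", lower = 1)
  check_number(D_slow, "D_slow", lower = 0)
  check_number(D_fast, "D_fast", lower = 0)
  if (D_slow > D_fast) abort_param("D_slow must not exceed D_fast")
  check_number(switch_prob, "switch_prob", lower = 0, upper = 1)
  check_number(sigma_loc, "sigma_loc", lower = 0)
  check_number(mean_track_len, "mean_track_len", lower = 1)
  if (!is.function(p_slow)) abort_param("p_slow must be a function(dose, recovery)")
  structure(list(frame_interval = frame_interval, n_frames = n_frames,
                 D_slow = D_slow, D_fast = D_fast, p_slow = p_slow,
                 switch_prob = switch_prob, sigma_loc = sigma_loc,
                 mean_track_len = mean_track_len,
                 emitters_per_cell = emitters_per_cell, seed = seed),
            class = "track_sim_config")
}

#' Simulate labelled cell masks with known shape descriptors
#'
#' Places non-overlapping filled ellipses of given area and aspect ratio
#' at random positions and orientations, rasterized on a pixel grid.
#' The returned truth table enables oracle tests of the morphology
#' operations.
#'
#' @param n_cells Number of cells to place.
#' @param area_um2 Cell area, um^2 (default 4, scalar or per cell).
#' @param aspect_ratio Major/minor axis ratio >= 1 (default 2).
#' @param pixel_size Pixel edge, nm (default 107).
#' @param dim_px Field size `c(rows, cols)` in pixels (default 512 x 512).
#' @param margin_px Clear border kept around each ellipse, px.
#' @param max_tries Placement retries before a capacity error.
#' @param seed RNG seed.
#' @return List with `mask` (a [label_mask()]) and `truth`
#'   (`data.frame`: label, area_um2, aspect_ratio, cx_nm, cy_nm, theta).
#' @export
simulate_cell_masks <- function(n_cells, area_um2 = 4, aspect_ratio = 2,
                                pixel_size = 107, dim_px = c(512, 512),
                                margin_px = 2, max_tries = 200, seed = NULL) {
  check_number(n_cells, "n_cells", lower = 1)
  if (any(area_um2 <= 0)) abort_param("area_um2 must be > 0")
  if (any(aspect_ratio < 1)) abort_param("aspect_ratio must be >= 1")
  area_um2 <- rep_len(area_um2, n_cells)
  aspect_ratio <- rep_len(aspect_ratio, n_cells)
  with_seed(seed, {
    nr <- dim_px[1]; nc <- dim_px[2]
    m <- matrix(0L, nr, nc)
    ps_um <- pixel_size / 1000
    truth <- vector("list", n_cells)
    # pixel centers in nm
    cx <- (col(m) - 0.5) * pixel_size
    cy <- (row(m) - 0.5) * pixel_size
    for (i in seq_len(n_cells)) {
      b_um <- sqrt(area_um2[i] / (pi * aspect_ratio[i]))
      a_um <- aspect_ratio[i] * b_um
      a <- a_um * 1000; b <- b_um * 1000  # nm
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        theta <- stats::runif(1, 0, pi)
        x0 <- stats::runif(1, a + margin_px * pixel_size,
                           nc * pixel_size - a - margin_px * pixel_size)
        y0 <- stats::runif(1, a + margin_px * pixel_size,
                           nr * pixel_size - a - margin_px * pixel_size)
        if (x0 <= 0 || y0 <= 0 || !is.finite(x0) || !is.finite(y0))
          abort_param("cell does not fit in the field; enlarge dim_px")
        dx <- cx - x0; dy <- cy - y0
        u <- dx * cos(theta) + dy * sin(theta)
        v <- -dx * sin(theta) + dy * cos(theta)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        # demand a clear margin to the neighbours
        ug <- dx * cos(theta) + dy * sin(theta)
        grown <- (ug / (a + margin_px * pixel_size))^2 +
          (v / (b + margin_px * pixel_size))^2 <= 1
        if (!any(m[grown] != 0L)) {
          m[inside] <- i
          truth[[i]] <- data.frame(label = i, area_um2 = area_um2[i],
                                   aspect_ratio = aspect_ratio[i],
                                   cx_nm = x0, cy_nm = y0, theta = theta)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort_param(sprintf(
          "could not place %d non-overlapping cells (failed at cell %d)",
          n_cells, i))
    }
    list(mask = label_mask(m, pixel_size), truth = do.call(rbind, truth))
  })
}

# label of the pixel containing point (x, y) in nm; 0 outside the field
mask_label_at <- function(mask, x, y) {
  ps <- attr(mask, "pixel_size")
  r <- floor(y / ps) + 1; cc <- floor(x / ps) + 1
  if (r < 1 || r > nrow(mask) || cc < 1 || cc > ncol(mask)) return(0L)
  mask[r, cc]
}

#' Simulate two-state diffusing emitters inside cells
#'
#' Each emitter performs a two-state Markov chain (slow/fast) with
#' per-frame switch propensity, Gaussian per-axis displacements of
#' variance `2 * D_state * dt`, reflection at the cell boundary, and is
#' observed with isotropic Gaussian localization noise. Track length is
#' geometric with the configured mean; the slow-state occupancy is
#' `config$p_slow(dose, recovery)`.
#'
#' @param config A [track_sim_config()].
#' @param mask A [label_mask()] with at least one cell.
#' @param dose UV dose, J/m^2 (default 0).
#' @param recovery Recovery time, min (default 0).
#' @param n_tracks Total number of emitters; default
#'   `emitters_per_cell * n_cells(mask)`.
#' @return List with `locs` (a `localizations` table: frame, x, y,
#'   precision) and `truth` (`data.frame`: track_id, frame, true_x,
#'   true_y, state with 1 = slow, label).
#' @export
simulate_tracks <- function(config, mask, dose = 0, recovery = 0,
                            n_tracks = NULL) {
  if (!inherits(config, "track_sim_config"))
    abort_param("config must come from track_sim_config()")
  labs <- setdiff(sort(unique(as.integer(mask))), 0L)
  if (!length(labs)) abort_input("mask has no foreground cells")
  p_slow <- config$p_slow(dose, recovery)
  check_number(p_slow, "p_slow(dose, recovery)", lower = 0, upper = 1)
  dt <- config$frame_interval
  sd_state <- sqrt(2 * c(config$D_slow, config$D_fast) * 1e6 * dt)  # nm
  n_tracks <- n_tracks %||% (config$emitters_per_cell * length(labs))
  ps <- attr(mask, "pixel_size")
  # per-label pixel index lists for uniform start placement
  idx_by_lab <- lapply(labs, function(l) which(mask == l))
  names(idx_by_lab) <- labs
  with_seed(config$seed, {
    lens <- 1L + stats::rgeom(n_tracks, prob = 1 / config$mean_track_len)
    starts <- sample.int(config$n_frames, n_tracks, replace = TRUE)
    lens <- pmin(lens, config$n_frames - starts + 1L)
    lab_of <- labs[sample.int(length(labs), n_tracks, replace = TRUE)]
    out <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      L <- lens[i]; lab <- lab_of[i]
      pix <- idx_by_lab[[as.character(lab)]][
        sample.int(length(idx_by_lab[[as.character(lab)]]), 1)]
      r0 <- (pix - 1L) %% nrow(mask) + 1L
      c0 <- (pix - 1L) %/% nrow(mask) + 1L
      x <- (c0 - 1 + stats::runif(1)) * ps
      y <- (r0 - 1 + stats::runif(1)) * ps
      # states: stationary two-state chain with occupancy p_slow
      st <- integer(L)
      st[1] <- if (stats::runif(1) < p_slow) 1L else 2L
      if (L > 1) {
        u <- stats::runif(L - 1)
        for (k in 2:L) {
          p_sw <- if (st[k - 1] == 1L) config$switch_prob * (1 - p_slow)
                  else config$switch_prob * p_slow
          st[k] <- if (u[k - 1] < p_sw) 3L - st[k - 1] else st[k - 1]
        }
      }
      xs <- numeric(L); ys <- numeric(L)
      xs[1] <- x; ys[1] <- y
      if (L > 1) {
        dxs <- stats::rnorm(L - 1) * sd_state[st[-1]]
        dys <- stats::rnorm(L - 1) * sd_state[st[-1]]
        for (k in 2:L) {
          nx <- xs[k - 1] + dxs[k - 1]; ny <- ys[k - 1] + dys[k - 1]
          if (mask_label_at(mask, nx, ny) != lab) {
            # reflect the offending step back into the cell
            cand <- list(c(xs[k - 1] - dxs[k - 1], ny),
                         c(nx, ys[k - 1] - dys[k - 1]),
                         c(xs[k - 1] - dxs[k - 1], ys[k - 1] - dys[k - 1]),
                         c(xs[k - 1], ys[k - 1]))
            for (cc in cand) {
              if (mask_label_at(mask, cc[1], cc[2]) == lab) {
                nx <- cc[1]; ny <- cc[2]; break
              }
            }
          }
          xs[k] <- nx; ys[k] <- ny
        }
      }
      obs_x <- xs + stats::rnorm(L, sd = config$sigma_loc)
      obs_y <- ys + stats::rnorm(L, sd = config$sigma_loc)
      out[[i]] <- data.frame(track_id = i,
                             frame = seq.int(starts[i], length.out = L),
                             x = obs_x, y = obs_y,
                             true_x = xs, true_y = ys,
                             state = st, label = lab)
    }
    all <- do.call(rbind, out)
    locs <- all[order(all$frame, all$track_id),
                c("frame", "x", "y"), drop = FALSE]
    locs$precision <- if (config$sigma_loc > 0) config$sigma_loc else NA_real_
    rownames(locs) <- NULL
    list(locs = as_localizations(locs),
         truth = all[c("track_id", "frame", "true_x", "true_y",
                       "state", "label")])
  })
}

#' Configuration for the plate-reader growth/fluorescence simulator
#'
#' @param N0 Initial OD600 (default 0.1).
#' @param K_cap Carrying-capacity OD (default 2; `Inf` for pure
#'   exponential growth).
#' @param mu Exponential growth rate, 1/h (default `log(2)/13`, a 13 h
#'   doubling time).
#' @param lag Lag time, h (default 5).
#' @param r_FP Fluorescent-protein production rate, a.u. per OD unit
#'   per h (default 10).
#' @param r_De Protein degradation rate, 1/h (default 0.02).
#' @param F0 Initial total fluorescence (default 0).
#' @param noise_cv Multiplicative measurement noise CV (default 0.02).
#' @param seed RNG seed.
#' @return A `growth_sim_config` list.
#' @export
growth_sim_config <- function(N0 = 0.1, K_cap = 2, mu = log(2) / 13,
                              lag = 5, r_FP = 10, r_De = 0.02, F0 = 0,
                              noise_cv = 0.02, seed = NULL) {
  for (nm in c("N0", "mu", "lag", "r_FP", "r_De", "F0", "noise_cv"))
    check_number(get(nm), nm, lower = 0)
  if (!(is.infinite(K_cap) || K_cap > N0))
    abort_param("K_cap must exceed N0")
  structure(list(N0 = N0, K_cap = K_cap, mu = mu, lag = lag, r_FP = r_FP,
                 r_De = r_De, F0 = F0, noise_cv = noise_cv, seed = seed),
            class = "growth_sim_config")
}

# lagged logistic OD curve
logistic_od <- function(cfg, t) {
  te <- pmax(t - cfg$lag, 0)
  if (is.infinite(cfg$K_cap)) return(cfg$N0 * exp(cfg$mu * te))
  cfg$K_cap * cfg$N0 /
    (cfg$N0 + (cfg$K_cap - cfg$N0) * exp(-cfg$mu * te))
}

#' Simulate a plate-reader time course
#'
#' OD follows a lagged logistic; total fluorescence F solves
#' `dF/dt = r_FP * N(t) - r_De * F` (production proportional to cell
#' mass, first-order degradation/dilution-free bulk signal). Both are
#' observed with multiplicative log-normal noise. In balanced
#' exponential growth F/OD plateaus at `r_FP / (mu + r_De)`.
#'
#' @param config A [growth_sim_config()].
#' @param t_grid Increasing time grid, h.
#' @return `data.frame` with `time_h`, `od600`, `fluor`, `well`.
#' @export
simulate_plate_reader <- function(config, t_grid) {
  if (!inherits(config, "growth_sim_config"))
    abort_param("config must come from growth_sim_config()")
  if (any(diff(t_grid) <= 0)) abort_param("t_grid must be increasing")
  od <- logistic_od(config, t_grid)
  rhs <- function(t, y, parms)
    list(config$r_FP * logistic_od(config, t) - config$r_De * y)
  tt <- t_grid
  if (tt[1] > 0) tt <- c(0, tt)
  sol <- deSolve::lsoda(y = config$F0, times = tt, func = rhs,
                        rtol = 1e-10, atol = 1e-12)
  f <- sol[match(t_grid, tt), 2]
  with_seed(config$seed, {
    data.frame(time_h = t_grid,
               od600 = od * rlnorm_cv(length(od), config$noise_cv),
               fluor = f * rlnorm_cv(length(f), config$noise_cv),
               well = "sim")
  })
}

#' Configuration for the CPD survival simulator
#'
#' @param K_true Decay constant, m^2/J (default 3e-3).
#' @param doses UV doses, J/m^2 (default `c(0, 100, 200, 400, 800, 1600)`).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param n_replicates Replicates per dose (default 1).
#' @param seed RNG seed.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(K_true = 3e-3,
                                doses = c(0, 100, 200, 400, 800, 1600),
                                noise_cv = 0.05, n_replicates = 1,
                                seed = NULL) {
  check_number(K_true, "K_true", lower = 0)
  if (any(doses < 0)) abort_param("doses must be >= 0")
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  structure(list(K_true = K_true, doses = doses, noise_cv = noise_cv,
                 n_replicates = n_replicates, seed = seed),
            class = "survival_sim_config")
}

#' Simulate a Poisson zero-event CPD survival table
#'
#' The fraction of plasmids with zero UV-induced lesions after dose D is
#' `exp(-K * D)`; multiplicative log-normal noise emulates gel-band
#' quantification error. Values are clipped to (0, 1].
#'
#' @param config A [survival_sim_config()].
#' @return `data.frame` with `dose_J_m2`, `replicate`, `intact_fraction`.
#' @export
simulate_cpd_survival <- function(config) {
  if (!inherits(config, "survival_sim_config"))
    abort_param("config must come from survival_sim_config()")
  with_seed(config$seed, {
    g <- expand.grid(replicate = seq_len(config$n_replicates),
                     dose_J_m2 = config$doses)
    frac <- exp(-config$K_true * g$dose_J_m2) *
      rlnorm_cv(nrow(g), config$noise_cv)
    data.frame(dose_J_m2 = g$dose_J_m2, replicate = g$replicate,
               intact_fraction = pmin(pmax(frac, .Machine$double.xmin), 1))
  })
}

#' Simulate a Langmuir compression isotherm from a compressibility profile
#'
#' Given a target compressibility-modulus profile `k(A)` (mN/m), the
#' surface pressure is obtained by integrating `dpi/dA = -k(A)/A` from
#' the largest molecular area (where pressure is zero) down the
#' compression branch.
#'
#' @param k_profile Function mapping molecular area (A^2) to modulus k
#'   (mN/m), `k >= 0`.
#' @param A_grid Strictly decreasing molecular-area grid, A^2.
#' @return `data.frame` with `area_A2`, `pressure_mN_m`.
#' @export
simulate_isotherm <- function(k_profile, A_grid) {
  if (any(diff(A_grid) >= 0))
    abort_param("A_grid must be strictly decreasing (compression branch)")
  k <- k_profile(A_grid)
  if (any(k < 0)) abort_param("k_profile must be non-negative")
  # integrate from A_max downwards: pi(A) = int_A^{Amax} k/A' dA'
  a_inc <- rev(A_grid)
  integrand <- rev(k) / a_inc
  pi_inc <- cumtrapz1(a_inc, integrand)
  pressure <- rev(pi_inc[length(pi_inc)] - pi_inc)
  pressure <- pressure - pressure[1]  # pi(A_max) = 0
  data.frame(area_A2 = A_grid, pressure_mN_m = pressure)
}
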