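make_plate <- function(seed = 3) {
  set.seed(seed)
  t <- seq(0, 48, by = 0.5)
  od_true <- 0.1 * 2^(pmax(t - 4, 0) / 12)
  f_true <- 30 * od_true
  rbind(
    data.frame(time_h = t, well = "S1", od600 = od_true + 0.04,
               fluor = f_true + 2),
    data.frame(time_h = t, well = "BLK", od600 = 0.04, fluor = 0),
    data.frame(time_h = t, well = "NEG", od600 = od_true + 0.04, fluor = 2))
}

test_that("blanking removes medium and autofluorescence signals exactly", {
  plate <- make_plate()
  res <- blank_and_normalize(plate, od_blank = "BLK", fluor_blank = "NEG")
  s <- res$growth[res$growth$well == "S1", ]
  t <- seq(0, 48, by = 0.5)
  expect_equal(s$od600, 0.1 * 2^(pmax(t - 4, 0) / 12), tolerance = 1e-12)
  f <- res$fluorescence[res$fluorescence$well == "S1", ]
  expect_equal(f$fluor, 30 * 0.1 * 2^(pmax(t - 4, 0) / 12),
               tolerance = 1e-12)
  # F equal to the control everywhere blanks to zero
  plate2 <- plate
  plate2$fluor[plate2$well == "S1"] <- 2
  res2 <- blank_and_normalize(plate2, "BLK", "NEG")
  expect_true(all(res2$fluorescence$fluor[res2$fluorescence$well == "S1"]
                  == 0))
})

test_that("F/OD is withheld below the OD floor, never infinite", {
  plate <- data.frame(time_h = rep(0:10, 2),
                      well = rep(c("S1", "BLK"), each = 11),
                      od600 = c(rep(0.011, 11), rep(0.001, 11)),
                      fluor = c(rep(5, 11), rep(0, 11)))
  res <- blank_and_normalize(plate, "BLK", "BLK", od_floor = 0.02)
  expect_true(all(is.na(res$fluorescence$fluor_per_od)))
  expect_true(all(is.finite(res$fluorescence$fluor)))
})

test_that("phase segmentation finds lag, exponential and stationary", {
  cfg <- growth_sim_config(N0 = 0.1, K_cap = 2, mu = log(2) / 12, lag = 5,
                           noise_cv = 0)
  t <- seq(0, 72, by = 0.5)
  pr <- simulate_plate_reader(cfg, t)
  ph <- segment_phases(t, pr$od600)
  expect_false(ph$no_growth)
  expect_lt(abs(ph$exp_start - 5), 1)
  expect_true(all(levels(ph$labels) ==
                    c("lag", "exponential", "stationary")))
  # pure exponential: the whole curve is exponential
  ph2 <- segment_phases(t, 0.1 * exp(0.06 * t))
  expect_true(all(ph2$labels == "exponential"))
  # constant OD: no growth flag
  ph3 <- segment_phases(t, rep(0.2, length(t)))
  expect_true(ph3$no_growth)
  expect_true(all(ph3$labels == "lag"))
  expect_error(segment_phases(1:5, 1:5), "10 time points")
})

test_that("doubling time is exact, scale-invariant and noise-robust", {
  t <- seq(0, 40, by = 0.5)
  od <- 0.1 * 2^(t / 12)
  expect_equal(doubling_time(t, od, window = seq_along(t)), 12,
               tolerance = 1e-12)
  expect_equal(doubling_time(t, 7.3 * od, window = seq_along(t)), 12,
               tolerance = 1e-12)
  expect_error(doubling_time(t, 0.5 * 2^(-t / 12), window = seq_along(t)),
               "non-positive")
  # noisy recovery: median over 20 seeds within 3%
  med <- median(vapply(1:20, function(s) {
    set.seed(s)
    doubling_time(t, od * rlnorm(length(t), 0, 0.02),
                  window = seq_along(t))
  }, numeric(1)))
  expect_lt(abs(med - 12) / 12, 0.03)
})

test_that("steady-state F/OD matches the kinetic equilibrium", {
  cfg <- growth_sim_config(N0 = 0.05, K_cap = Inf, mu = log(2) / 12,
                           lag = 0, r_FP = 10, r_De = 0.02, noise_cv = 0)
  t <- seq(0, 80, by = 0.5)
  pr <- simulate_plate_reader(cfg, t)
  fod <- pr$fluor / pr$od600
  ss <- steady_state_fluorescence(fod, t >= 60)
  plateau <- 10 / (log(2) / 12 + 0.02)
  expect_lt(abs(ss$mean - plateau) / plateau, 0.02)
  ss2 <- steady_state_fluorescence(rep(4.2, 10), 1:10)
  expect_equal(ss2$sd, 0)
  expect_error(steady_state_fluorescence(fod, integer(0)), "empty")
})

test_that("phosphate standards invert linearly with extrapolation flags", {
  std <- data.frame(nmol = c(0, 5, 10, 50, 100),
                    A820 = 0.01 * c(0, 5, 10, 50, 100) + 0.002)
  res <- phosphate_standard(std, c(0.25, 0.252, 1.5))
  expect_equal(res$estimates$nmol[1:2], c(24.8, 25.0), tolerance = 1e-9)
  expect_false(any(res$estimates$extrapolated[1:2]))
  expect_true(res$estimates$extrapolated[3])
  expect_equal(res$r_squared, 1)
  expect_error(phosphate_standard(std[1:2, ], 0.1), "3 standards")
  bad <- data.frame(nmol = c(0, 5, 10), A820 = c(0.3, 0.2, 0.1))
  expect_error(phosphate_standard(bad, 0.1), "slope")
})

test_that("compressibility modulus recovers analytic profiles", {
  A <- seq(80, 30, by = -0.5)
  iso <- data.frame(area_A2 = A, pressure_mN_m = 40 - 0.5 * A)
  k <- compressibility_modulus(iso)
  expect_equal(k$k_mN_m, 0.5 * k$area_A2, tolerance = 1e-9)
  expect_equal(k$k_mN_m[k$area_A2 == 50], 25, tolerance = 1e-9)

  # ideal-gas branch pi = c/A: k(A) = c/A = pi(A) for the offset-free law
  c0 <- 900
  iso2 <- data.frame(area_A2 = A, pressure_mN_m = c0 / A)
  k2 <- compressibility_modulus(iso2)
  interior <- 3:(nrow(k2) - 2)
  expect_lt(max(abs(k2$k_mN_m[interior] - c0 / k2$area_A2[interior]) /
                  (c0 / k2$area_A2[interior])), 0.01)

  # generator round-trip: known smooth k-profile recovered within 2%
  kp <- function(A) 30 + 0.4 * A
  iso3 <- simulate_isotherm(kp, seq(120, 40, by = -0.4))
  k3 <- compressibility_modulus(iso3)
  interior <- 5:(nrow(k3) - 4)
  expect_lt(max(abs(k3$k_mN_m[interior] - kp(k3$area_A2[interior])) /
                  kp(k3$area_A2[interior])), 0.02)

  dupe <- data.frame(area_A2 = c(80, 80, 70, 60, 50, 40),
                     pressure_mN_m = 1:6)
  expect_silent(compressibility_modulus(dupe))  # dedup keeps 5 points
  expect_error(compressibility_modulus(dupe[1:5, ]), "5 distinct")
})

test_that("FTIR preprocessing normalizes, differentiates and finds bands", {
  wn <- seq(1000, 3100, by = 2)
  ab <- exp(-(wn - 1650)^2 / (2 * 15^2)) +
    0.8 * exp(-(wn - 2925)^2 / (2 * 12^2))
  fp <- ftir_preprocess(data.frame(wavenumber_cm = wn, absorbance = ab))
  # self-normalization: value 1 at the reference band
  i_ref <- which.min(abs(fp$spectrum$wavenumber_cm - 2925))
  expect_equal(max(fp$spectrum$normalized[abs(wn - 2925) <= 20]), 1)
  # second-derivative minima at the band centers, within one grid step
  expect_true(any(abs(fp$peaks$wavenumber_cm - 1650) <= 2))
  expect_true(any(abs(fp$peaks$wavenumber_cm - 2925) <= 2))
  # two identical spectra have identically zero second-derivative difference
  fp2 <- ftir_preprocess(data.frame(wavenumber_cm = wn, absorbance = ab))
  expect_true(all(fp$spectrum$second_deriv - fp2$spectrum$second_deriv
                  == 0))
  expect_error(ftir_preprocess(data.frame(wavenumber_cm = wn,
                                          absorbance = ab), ref_peak = 500),
               "outside")
})
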