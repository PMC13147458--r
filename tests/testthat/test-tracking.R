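test_that("acquisition filter removes exactly the bleaching lead-in", {
  set.seed(3)
  locs <- as_localizations(data.frame(
    frame = sample(1:10000, 5000, replace = TRUE),
    x = runif(5000, 0, 1e4), y = runif(5000, 0, 1e4)))
  f <- filter_acquisition(locs, 1000)
  expect_equal(nrow(f), sum(locs$frame > 1000))
  expect_true(all(f$frame > 1000))
  # frames keep their original indices
  expect_setequal(f$frame, unique(locs$frame[locs$frame > 1000]))

  expect_equal(nrow(filter_acquisition(locs, 0)), nrow(locs))
  low <- as_localizations(data.frame(frame = 1:10, x = 1:10, y = 1:10))
  expect_equal(nrow(filter_acquisition(low, 1000)), 0L)
})

test_that("well-separated emitters link perfectly", {
  set.seed(4)
  n_frames <- 100
  centers <- cbind(c(0, 5000, 10000), c(0, 5000, 0))
  rows <- do.call(rbind, lapply(1:3, function(e) {
    x <- centers[e, 1] + cumsum(rnorm(n_frames, 0, 50))
    y <- centers[e, 2] + cumsum(rnorm(n_frames, 0, 50))
    data.frame(frame = 1:n_frames, x = x, y = y, emitter = e)
  }))
  locs <- as_localizations(rows[order(rows$frame), ])
  tr <- link_localizations(locs, max_jump = 500)
  expect_equal(length(unique(tr$track_id)), 3L)
  # each reconstructed track carries exactly one true emitter
  m <- merge(tr, locs[c("frame", "x", "emitter")], by = c("frame", "x"))
  purity <- tapply(m$emitter, m$track_id, function(v) length(unique(v)))
  expect_true(all(purity == 1))
})

test_that("linking matches exhaustive assignment on small instances", {
  for (s in 1:40) {
    set.seed(s)
    n_frames <- 4
    rows <- do.call(rbind, lapply(1:n_frames, function(f) {
      k <- sample(0:4, 1)
      if (k == 0) return(NULL)
      data.frame(frame = f, x = runif(k, 0, 600), y = runif(k, 0, 600))
    }))
    if (is.null(rows) || !nrow(rows)) next
    locs <- as_localizations(rows)
    max_jump <- 300
    tr <- link_localizations(locs, max_jump = max_jump, min_len = 1)
    got <- link_cost_summary(tr)
    # frame-by-frame exhaustive oracle
    exp_links <- 0L; exp_cost <- 0
    for (f in 1:(n_frames - 1)) {
      a <- rows[rows$frame == f, , drop = FALSE]
      b <- rows[rows$frame == f + 1, , drop = FALSE]
      if (!nrow(a) || !nrow(b)) next
      cost <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
        (a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2)
      cost[cost > max_jump^2] <- Inf
      o <- oracle_match(cost)
      exp_links <- exp_links + o$n_links; exp_cost <- exp_cost + o$cost
    }
    expect_equal(got$n_links, exp_links, info = paste("seed", s))
    expect_equal(got$cost, exp_cost, tolerance = 1e-9,
                 info = paste("seed", s))
  }
})

test_that("linking degenerates and bounds behave", {
  one <- as_localizations(data.frame(frame = 5L, x = 0, y = 0))
  expect_equal(nrow(link_localizations(one, 500)), 0L)
  expect_equal(nrow(link_localizations(one[0, ], 500)), 0L)

  # no created jump ever exceeds max_jump
  set.seed(9)
  locs <- as_localizations(data.frame(
    frame = rep(1:50, each = 6),
    x = runif(300, 0, 3000), y = runif(300, 0, 3000)))
  tr <- link_localizations(locs, max_jump = 400)
  if (nrow(tr)) {
    jd <- attr(compute_jumps(tr), "jumps")$jd
    expect_true(all(jd <= 400 + 1e-9))
  }
})

test_that("jump distances, MJD and weights follow their definitions", {
  tr <- data.frame(track_id = 1L, frame = 1:2, x = c(0, 3), y = c(0, 4))
  st <- compute_jumps(tr)
  expect_equal(attr(st, "jumps")$jd, 5)

  tr2 <- data.frame(track_id = 1L, frame = 1:4,
                    x = c(0, 5, 10, 15), y = 0)
  st2 <- compute_jumps(tr2)
  expect_equal(st2$mjd, 5)
  expect_equal(st2$weight, 3L)

  # gap-spanning links are excluded from JD
  tr3 <- data.frame(track_id = 1L, frame = c(1, 2, 4), x = c(0, 3, 30),
                    y = c(0, 4, 40))
  st3 <- compute_jumps(tr3)
  expect_equal(attr(st3, "jumps")$jd, 5)
  expect_equal(st3$weight, 1L)

  # single-localization tracks are dropped with a warning
  tr4 <- rbind(tr2, data.frame(track_id = 2L, frame = 1L, x = 0, y = 0))
  expect_warning(st4 <- compute_jumps(tr4), "excluded")
  expect_equal(attr(st4, "n_excluded"), 1L)
  expect_equal(st4$track_id, 1L)

  # min(JD) <= MJD <= max(JD) on random tracks
  set.seed(12)
  rt <- data.frame(track_id = rep(1:20, each = 10),
                   frame = rep(1:10, 20),
                   x = rnorm(200, 0, 80), y = rnorm(200, 0, 80))
  strt <- compute_jumps(rt)
  j <- attr(strt, "jumps")
  rng <- tapply(j$jd, j$track_id, range)
  for (id in strt$track_id) {
    expect_gte(strt$mjd[strt$track_id == id], rng[[as.character(id)]][1])
    expect_lte(strt$mjd[strt$track_id == id], rng[[as.character(id)]][2])
  }
})

test_that("wMJD weighting pools tracks by jump count", {
  tr <- rbind(data.frame(track_id = 1L, frame = 1:2, x = c(0, 50), y = 0),
              data.frame(track_id = 2L, frame = 1:4,
                         x = c(0, 100, 200, 300), y = 0))
  w <- build_wmjd(tr, "demo")
  expect_equal(sort(w$mjd_nm), c(50, 100))
  expect_equal(w$weight[order(w$mjd_nm)], c(1L, 3L))
  expect_equal(wmjd_mean(w), (50 + 300) / 4)

  # all weights one: weighted mean equals the plain mean
  w1 <- make_wmjd(50, seed = 1)
  expect_equal(wmjd_mean(w1), mean(w1$mjd_nm))

  expect_error(build_wmjd(tr[0, ]), "no tracks")
})

test_that("two-state wMJD mean falls between the state means", {
  mask <- huge_cell_mask()
  per_state_mean <- function(D) sqrt(pi * D * 1e6 * 0.02)
  cfg <- track_sim_config(D_slow = 0.02, D_fast = 0.3, sigma_loc = 0,
                          switch_prob = 0, mean_track_len = 10,
                          p_slow = function(dose, recovery) 0.25,
                          seed = 41)
  sim <- simulate_tracks(cfg, mask, n_tracks = 1500)
  tr <- data.frame(track_id = sim$truth$track_id, frame = sim$truth$frame,
                   x = sim$truth$true_x, y = sim$truth$true_y)
  w <- suppressWarnings(build_wmjd(tr))
  m <- wmjd_mean(w)
  expect_gt(m, per_state_mean(0.02))
  expect_lt(m, per_state_mean(0.3))
  # only a quarter of tracks are slow: the mean sits nearer the fast mean
  expect_gt(m, mean(c(per_state_mean(0.02), per_state_mean(0.3))))
})

test_that("jump-distance population split follows the 250/500 thresholds", {
  tr <- data.frame(track_id = rep(1:3, each = 2),
                   frame = rep(1:2, 3),
                   x = c(0, 100, 0, 300, 0, 600), y = 0)
  sp <- split_populations(tr)
  expect_equal(nrow(sp$slow), 2L)   # endpoints of the 100 nm jump
  expect_equal(nrow(sp$fast), 2L)   # endpoints of the 300 nm jump
  expect_equal(nrow(sp$combined), 4L)
  expect_false(600 %in% sp$combined$x)  # >= 500 nm excluded

  # zero-length jumps are all slow
  tz <- data.frame(track_id = 1L, frame = 1:5, x = 0, y = 0)
  spz <- split_populations(tz)
  expect_equal(nrow(spz$slow), 5L)
  expect_equal(nrow(spz$fast), 0L)

  # shared endpoint appears once per population table
  ts <- data.frame(track_id = 1L, frame = 1:3, x = c(0, 100, 400), y = 0)
  sps <- split_populations(ts)
  expect_equal(nrow(sps$slow), 2L)
  expect_equal(nrow(sps$fast), 2L)
  expect_equal(nrow(sps$combined), 3L)

  expect_error(split_populations(tr, 250, 250), "slow_max")
})

test_that("diffusion coefficient is recovered from the mean jump distance", {
  mask <- huge_cell_mask()
  cfg <- track_sim_config(D_slow = 0.15, D_fast = 0.15, sigma_loc = 0,
                          mean_track_len = 60000, n_frames = 70000,
                          seed = 51)
  sim <- simulate_tracks(cfg, mask, n_tracks = 2)
  jd <- unlist(lapply(split(sim$truth, sim$truth$track_id), function(t_)
    sqrt(diff(t_$true_x)^2 + diff(t_$true_y)^2)))
  D_hat <- diffusion_from_mjd(mean(jd), 0.02)
  expect_lt(abs(D_hat - 0.15) / 0.15, 0.03)
})

test_that("links on sparse synthetic data match ground truth", {
  mask <- simulate_cell_masks(6, area_um2 = 5, aspect_ratio = 2,
                              pixel_size = 107, seed = 61)$mask
  cfg <- track_sim_config(sigma_loc = 15, mean_track_len = 10,
                          n_frames = 4000, seed = 62)
  sim <- simulate_tracks(cfg, mask, n_tracks = 400)
  tr <- link_localizations(sim$locs, max_jump = 800, min_len = 2)
  # map each linked localization back to its true emitter via position
  key <- paste(sim$locs$frame, round(sim$locs$x, 6))
  truth_sorted <- sim$truth[order(sim$truth$frame, sim$truth$track_id), ]
  # observed locs were sorted by (frame, track); use that ordering
  true_id <- truth_sorted$track_id
  tr_key <- paste(tr$frame, round(tr$x, 6))
  tid <- true_id[match(tr_key, key)]
  ok <- 0L; total <- 0L
  for (id in unique(tr$track_id)) {
    rows <- which(tr$track_id == id)
    if (length(rows) < 2) next
    consec <- diff(tr$frame[rows]) == 1
    ok <- ok + sum(consec & diff(tid[rows]) == 0)
    total <- total + sum(consec)
  }
  expect_gt(ok / total, 0.99)
})
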