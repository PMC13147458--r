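# Trajectory building and jump-distance statistics.

#' Discard the photobleaching lead-in of an acquisition
#'
#' sptPALM acquisitions start with a bleaching period recorded only to
#' extinguish background fluorophores; those frames are removed before
#' tracking. Remaining frames keep their original indices.
#'
#' @param locs A `localizations` table.
#' @param discard_frames Number of leading frames to discard (all
#'   localizations with `frame <= discard_frames`; default 1000).
#' @return The filtered `localizations` table.
#' @export
filter_acquisition <- function(locs, discard_frames = 1000) {
  check_number(discard_frames, "discard_frames", lower = 0)
  out <- locs[locs$frame > discard_frames, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(locs)
  out
}

#' Link localizations into trajectories
#'
#' Frame-to-frame linking by optimal bipartite assignment: between each
#' consecutive frame pair, candidate links are pairs closer than
#' `max_jump`; among assignments of maximal link count the one with
#' minimal total squared displacement is chosen (Hungarian algorithm).
#' Unmatched localizations start new tracks. With `max_gap = 0`
#' (default) a track ends at its first missed frame.
#'
#' @param locs A `localizations` table.
#' @param max_jump Hard search radius, nm.
#' @param max_gap Allowed missed frames inside a track (default 0).
#' @param min_len Minimum track length in localizations (default 2);
#'   shorter tracks are dropped.
#' @return A `tracks` table (`track_id`, `frame`, `x`, `y`, `precision`).
#' @export
link_localizations <- function(locs, max_jump, max_gap = 0, min_len = 2) {
  check_number(max_jump, "max_jump", lower = 0, allow_equal = FALSE)
  check_number(max_gap, "max_gap", lower = 0)
  check_number(min_len, "min_len", lower = 1)
  n <- nrow(locs)
  if (n == 0L)
    return(validate_tracks(data.frame(track_id = integer(), frame = integer(),
                                      x = numeric(), y = numeric())))
  ord <- order(locs$frame, seq_len(n))
  locs <- locs[ord, , drop = FALSE]
  frame <- locs$frame; x <- locs$x; y <- locs$y
  track <- integer(n)
  next_id <- 0L
  frames <- sort(unique(frame))
  idx_by_frame <- split(seq_len(n), frame)
  # active tracks: last localization row index per open track
  open_rows <- integer(0)
  open_frame <- integer(0)
  for (f in frames) {
    cur <- idx_by_frame[[as.character(f)]]
    keep <- open_frame >= f - 1 - max_gap
    open_rows <- open_rows[keep]; open_frame <- open_frame[keep]
    assigned <- rep(NA_integer_, length(cur))
    if (length(open_rows)) {
      cost <- outer(open_rows, cur, function(i, j)
        (x[i] - x[j])^2 + (y[i] - y[j])^2)
      cost[cost > max_jump^2] <- Inf
      sol <- solve_assignment(cost)
      for (r in seq_along(sol)) {
        if (!is.na(sol[r])) {
          j <- cur[sol[r]]
          track[j] <- track[open_rows[r]]
          assigned[sol[r]] <- r
        }
      }
      taken <- !is.na(sol)
      open_rows <- open_rows[!taken]; open_frame <- open_frame[!taken]
    }
    new <- which(is.na(assigned))
    if (length(new)) {
      track[cur[new]] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    open_rows <- c(open_rows, cur)
    open_frame <- c(open_frame, rep(f, length(cur)))
  }
  len <- table(track)
  keep_ids <- as.integer(names(len)[len >= min_len])
  sel <- track %in% keep_ids
  out <- data.frame(track_id = match(track[sel], sort(unique(track[sel]))),
                    frame = frame[sel], x = x[sel], y = y[sel])
  if ("precision" %in% names(locs)) out$precision <- locs$precision[sel]
  validate_tracks(out)
}

#' Per-track jump distances and mean jump distance
#'
#' Computes Euclidean jump distances (JD) between consecutive-frame
#' localizations of each track, the per-track mean jump distance (MJD)
#' and its weight (number of jumps). Jumps spanning a frame gap are
#' excluded; tracks with a single localization are dropped with a count
#' reported in attribute `n_excluded`.
#'
#' @param tracks A `tracks` table.
#' @return `data.frame` of class `track_stats` with one row per retained
#'   track: `track_id`, `mjd` (nm), `weight`; attribute `jumps` holds a
#'   `data.frame` of all individual jumps (`track_id`, `frame_from`,
#'   `jd`) and attribute `n_excluded` the dropped single-localization
#'   track count.
#' @export
compute_jumps <- function(tracks) {
  tracks <- validate_tracks(tracks)
  if (!nrow(tracks)) {
    out <- data.frame(track_id = integer(), mjd = numeric(),
                      weight = integer())
    attr(out, "jumps") <- data.frame(track_id = integer(),
                                     frame_from = integer(), jd = numeric())
    attr(out, "n_excluded") <- 0L
    class(out) <- c("track_stats", "data.frame")
    return(out)
  }
  sp <- split(tracks[c("frame", "x", "y")], tracks$track_id)
  jump_list <- lapply(names(sp), function(id) {
    tr <- sp[[id]]
    if (nrow(tr) < 2L) return(NULL)
    consec <- diff(tr$frame) == 1L
    if (!any(consec)) return(NULL)
    i <- which(consec)
    data.frame(track_id = as.integer(id), frame_from = tr$frame[i],
               jd = sqrt(diff(tr$x)[i]^2 + diff(tr$y)[i]^2))
  })
  n_single <- sum(vapply(sp, nrow, integer(1)) < 2L)
  if (n_single > 0)
    warning(sprintf("%d single-localization track(s) excluded", n_single))
  jumps <- do.call(rbind, jump_list)
  if (is.null(jumps))
    jumps <- data.frame(track_id = integer(), frame_from = integer(),
                        jd = numeric())
  agg <- if (nrow(jumps))
    stats::aggregate(jd ~ track_id, jumps,
                     function(v) c(mean(v), length(v)))
  else NULL
  out <- if (!is.null(agg))
    data.frame(track_id = agg$track_id, mjd = agg$jd[, 1],
               weight = as.integer(agg$jd[, 2]))
  else data.frame(track_id = integer(), mjd = numeric(), weight = integer())
  attr(out, "jumps") <- jumps
  attr(out, "n_excluded") <- n_single
  class(out) <- c("track_stats", "data.frame")
  out
}

#' Build a weighted mean-jump-distance dataset
#'
#' One entry per track: its MJD and a frequency weight equal to the
#' number of jumps, so longer (better-estimated) tracks count more in
#' the rank statistics downstream.
#'
#' @param tracks A `tracks` table or a `track_stats` result from
#'   [compute_jumps()].
#' @param condition Condition label, e.g. `"100J_180min"`.
#' @return `data.frame` of class `wmjd`: `condition`, `mjd_nm`, `weight`.
#' @export
build_wmjd <- function(tracks, condition = "untreated") {
  st <- if (inherits(tracks, "track_stats")) tracks else compute_jumps(tracks)
  if (!nrow(st)) abort_input("no tracks with at least one jump")
  out <- data.frame(condition = condition, mjd_nm = st$mjd,
                    weight = as.integer(st$weight))
  class(out) <- c("wmjd", "data.frame")
  out
}

#' Weighted mean of a wMJD dataset
#' @param x A `wmjd` dataset.
#' @return The jump-count-weighted mean MJD, nm.
#' @export
wmjd_mean <- function(x) sum(x$mjd_nm * x$weight) / sum(x$weight)

#' Split localizations by jump-distance population
#'
#' Classifies each jump by its length: below `slow_max` it belongs to
#' the slow (binding-like) population, between `slow_max` and `fast_max`
#' to the fast (scanning) population, at or above `fast_max` it is
#' excluded. Both endpoints of a jump carry its class; a localization
#' shared by jumps of different classes appears once in each
#' corresponding table.
#'
#' @param tracks A `tracks` table.
#' @param slow_max Slow/fast threshold, nm (default 250).
#' @param fast_max Upper cutoff, nm (default 500).
#' @return List of three `localizations` tables: `slow`, `fast`,
#'   `combined` (union of both).
#' @export
split_populations <- function(tracks, slow_max = 250, fast_max = 500) {
  if (!(slow_max > 0 && fast_max > slow_max))
    abort_param("need 0 < slow_max < fast_max")
  tracks <- validate_tracks(tracks)
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  take <- function(rows) {
    out <- data.frame(frame = tracks$frame[rows], x = tracks$x[rows],
                      y = tracks$y[rows])
    if ("precision" %in% names(tracks)) out$precision <- tracks$precision[rows]
    out
  }
  slow_rows <- integer(0); fast_rows <- integer(0)
  for (rows in sp) {
    if (length(rows) < 2L) next
    consec <- diff(tracks$frame[rows]) == 1L
    jd <- sqrt(diff(tracks$x[rows])^2 + diff(tracks$y[rows])^2)
    for (k in which(consec)) {
      ends <- rows[c(k, k + 1L)]
      if (jd[k] < slow_max) slow_rows <- c(slow_rows, ends)
      else if (jd[k] < fast_max) fast_rows <- c(fast_rows, ends)
    }
  }
  slow_rows <- sort(unique(slow_rows))
  fast_rows <- sort(unique(fast_rows))
  comb_rows <- sort(unique(c(slow_rows, fast_rows)))
  list(slow = as_localizations(take(slow_rows)),
       fast = as_localizations(take(fast_rows)),
       combined = as_localizations(take(comb_rows)))
}

#' Estimate a diffusion coefficient from mean jump distance
#'
#' For free 2D Brownian motion observed at interval `dt` without
#' localization error, jump distances are Rayleigh with mean
#' `sqrt(pi * D * dt)`; inverting gives `D = mjd^2 / (pi * dt)`.
#'
#' @param mean_jd Mean jump distance, nm.
#' @param dt Frame interval, s.
#' @return Apparent diffusion coefficient, um^2/s.
#' @export
diffusion_from_mjd <- function(mean_jd, dt) {
  check_number(dt, "dt", lower = 0, allow_equal = FALSE)
  (mean_jd^2 / (pi * dt)) / 1e6
}
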