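# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Mann-Whitney U by explicit pair counting with the half-credit tie rule
oracle_mwu <- function(a, b) {
  U_a <- 0
  for (x in a) for (y in b)
    U_a <- U_a + if (x > y) 1 else if (x == y) 0.5 else 0
  list(U_a = U_a, U_b = length(a) * length(b) - U_a)
}

# Exhaustive bipartite matching: maximize the number of allowed links
# (finite cost), then minimize the total cost. Returns list(n_links, cost).
oracle_match <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(n_links = -1L, cost = Inf)
  rec <- function(i, used, links, total) {
    if (i > n) {
      if (links > best$n_links ||
          (links == best$n_links && total < best$cost - 1e-12))
        best <<- list(n_links = links, cost = total)
      return(invisible())
    }
    rec(i + 1L, used, links, total)  # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j]))
        rec(i + 1L, replace(used, j, TRUE), links + 1L, total + cost[i, j])
    }
  }
  rec(1L, rep(FALSE, m), 0L, 0)
  best
}

# total linked-pair count and squared-displacement cost of a track table,
# per consecutive frame pair (for comparison against oracle_match)
link_cost_summary <- function(tracks) {
  n_links <- 0L; total <- 0
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) next
    consec <- diff(tr$frame) == 1
    n_links <- n_links + sum(consec)
    total <- total + sum((diff(tr$x)^2 + diff(tr$y)^2)[consec])
  }
  list(n_links = n_links, cost = total)
}

# quick wMJD dataset builder
make_wmjd <- function(n, meanlog = log(100), sdlog = 0.4, weight = 1L,
                      condition = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- data.frame(condition = condition,
                  mjd_nm = stats::rlnorm(n, meanlog, sdlog),
                  weight = as.integer(rep_len(weight, n)))
  class(d) <- c("wmjd", "data.frame")
  d
}

# standard simulation field for tracking tests: one huge round cell so
# the boundary never matters
huge_cell_mask <- function() {
  m <- matrix(0L, 700, 700)
  for (r in seq_len(700)) {
    w <- 330^2 - (r - 350.5)^2
    if (w > 0) {
      c1 <- ceiling(350.5 - sqrt(w)); c2 <- floor(350.5 + sqrt(w))
      m[r, max(1, c1):min(700, c2)] <- 1L
    }
  }
  label_mask(m, 107)
}
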