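# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_halospt <- function(msg, class) {
  stop(structure(class = c(class, "halospt_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_format <- function(msg) stop_halospt(msg, "halospt_format_error")
abort_input  <- function(msg) stop_halospt(msg, "halospt_input_error")
abort_param  <- function(msg) stop_halospt(msg, "halospt_param_error")
abort_data   <- function(msg) stop_halospt(msg, "halospt_data_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_param(sprintf("'%s' must be a single finite number", name))
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok)
    abort_param(sprintf("'%s' = %g outside allowed range [%g, %g]",
                        name, x, lower, upper))
  invisible(x)
}

# Solve the rectangular linear assignment problem: minimize sum of
# cost[i, match(i)] over injective row -> column matchings of maximal
# cardinality among allowed pairs (finite cost).  Forbidden pairs carry
# Inf; internally replaced by a cost large enough that the optimum first
# maximizes the number of allowed links, then minimizes total cost.
# Classic O(n^3) Jonker-Volgenant style shortest augmenting path solver.
# Returns an integer vector of length nrow(cost): column index or NA.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  finite <- is.finite(cost)
  if (!any(finite)) return(rep(NA_integer_, n))
  big <- (sum(cost[finite]) + 1) * 2 + max(cost[finite])
  # pad to square so every row/column can be assigned
  k <- max(n, m)
  C <- matrix(big, k, k)
  C[seq_len(n), seq_len(m)] <- ifelse(finite, cost, big)
  # shortest augmenting path (Hungarian), potentials u/v
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1)  # p[j]: row assigned to column j (0 = none)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, k + 1)
    used <- rep(FALSE, k + 1)
    way <- integer(k + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(k + 1L)) {
        if (!used[j]) {
          cur <- C[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(k + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in 2L:(k + 1L)) {
    r <- p[j]
    if (r >= 1L && r <= n && (j - 1L) <= m && is.finite(cost[r, j - 1L]))
      ans[r] <- j - 1L
  }
  ans
}

# trapezoidal cumulative integral of y over x
cumtrapz1 <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}
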