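# Independent oracles and small fixture builders used across the suite.

# Brute-force network-event oracle: evaluates the active-cell fraction on
# a dense set of candidate window starts (all piecewise-constant
# breakpoints plus midpoints), classifies every onset by exhaustive
# search, links related onsets by exhaustive pairwise shared-window
# search with explicit transitive closure, and merges overlapping spans.
# Deliberately written independently of detect_gdps().
oracle_gdps <- function(onsets, w = 0.5, frac = 0.2) {
  n_cells <- length(onsets)
  ev_t <- unlist(onsets, use.names = FALSE)
  ev_c <- rep(seq_along(onsets), lengths(onsets))
  o <- order(ev_t); ev_t <- ev_t[o]; ev_c <- ev_c[o]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_members = integer(0))
  if (!length(ev_t)) return(empty)
  bp <- sort(unique(c(ev_t, ev_t - w)))
  ts <- sort(unique(c(bp, (head(bp, -1) + tail(bp, -1)) / 2)))
  n_active <- vapply(ts, function(t0) {
    sum(vapply(onsets, function(oo) any(oo >= t0 & oo <= t0 + w),
               logical(1)))
  }, numeric(1))
  ok <- n_active >= frac * n_cells
  related <- vapply(ev_t, function(t0) {
    any(ok[ts >= t0 - w & ts <= t0])
  }, logical(1))
  if (!any(related)) return(empty)
  rt <- ev_t[related]; rc <- ev_c[related]
  n <- length(rt)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      lo <- max(rt[i], rt[j]) - w
      hi <- min(rt[i], rt[j])
      if (lo <= hi) adj[i, j] <- any(ok[ts >= lo & ts <= hi])
    }
  }
  comp <- seq_len(n)
  repeat {
    nw <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), integer(1))
    if (identical(nw, comp)) break
    comp <- nw
  }
  ev <- do.call(rbind, lapply(unique(comp), function(g) {
    ii <- comp == g
    data.frame(start = min(rt[ii]), end = max(rt[ii]),
               n_members = length(unique(rc[ii])))
  }))
  ev <- ev[order(ev$start), , drop = FALSE]
  # merge overlapping spans
  out <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      last <- nrow(out)
      if (ev$start[i] <= out$end[last]) {
        out$end[last] <- max(out$end[last], ev$end[i])
      } else out <- rbind(out, ev[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

# Onsets classified as network-related by the exhaustive search (used for
# the fraction-monotonicity property).
oracle_related_onsets <- function(onsets, w = 0.5, frac = 0.2) {
  n_cells <- length(onsets)
  ev_t <- sort(unlist(onsets, use.names = FALSE))
  if (!length(ev_t)) return(numeric(0))
  bp <- sort(unique(c(ev_t, ev_t - w)))
  ts <- sort(unique(c(bp, (head(bp, -1) + tail(bp, -1)) / 2)))
  n_active <- vapply(ts, function(t0) {
    sum(vapply(onsets, function(oo) any(oo >= t0 & oo <= t0 + w),
               logical(1)))
  }, numeric(1))
  ok <- n_active >= frac * n_cells
  ev_t[vapply(ev_t, function(t0) any(ok[ts >= t0 - w & ts <= t0]),
              logical(1))]
}

# Random sparse raster for the oracle-equivalence property.
random_raster <- function(seed, n_cells = NULL, duration = 60) {
  set.seed(seed)
  if (is.null(n_cells)) n_cells <- sample(5:20, 1)
  onsets <- lapply(seq_len(n_cells), function(i) {
    sort(runif(rpois(1, 2.5), 0, duration))
  })
  cat_raster(onsets, duration)
}

# Independent quadratic least-squares fit over a centered window,
# evaluated at the midpoint (oracle for the Savitzky-Golay baseline).
quadfit_at_center <- function(y) {
  n <- length(y)
  x <- seq_len(n) - (n + 1) / 2
  X <- cbind(1, x, x^2)
  beta <- solve(crossprod(X), crossprod(X, y))
  beta[1] # value at x = 0
}

# Closed-form membrane step response (R in MOhm, C in pF, I in pA).
rc_step_response <- function(t, R, C, E, I) {
  tau <- R * C * 1e-6
  E + I * R / 1000 * (1 - exp(-t / tau))
}
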