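# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an independent child seed from a master seed
#'
#' Each planted event class in the synthetic generators draws from its own
#' seed stream so that, e.g., regenerating a dataset with a different
#' network-event rate leaves the per-cell background events untouched.
#'
#' @param seed master integer seed
#' @param stream small non-negative integer identifying the stream
#' @return an integer seed < 2^31
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stream * 99991) %% 2147483587)
}

# Run code with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Generate 1/f^alpha ("pink") noise
#'
#' Spectral-synthesis generator: white Gaussian noise is shaped in the
#' frequency domain by f^(-alpha/2) and transformed back, then rescaled to
#' the requested standard deviation. alpha = 0 gives white noise, alpha = 1
#' the canonical pink spectrum of extracellular background activity.
#'
#' @param n number of samples
#' @param alpha spectral exponent (power ~ 1/f^alpha)
#' @param sd target standard deviation of the output
#' @return numeric vector of length `n`
#' @export
pink_noise <- function(n, alpha = 1, sd = 1) {
  stopifnot(n >= 1, alpha >= 0, sd >= 0)
  if (sd == 0) return(numeric(n))
  if (alpha == 0) return(rnorm(n, sd = sd))
  w <- rnorm(n)
  sp <- fft(w)
  # frequency index of each FFT bin (two-sided)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  scale <- c(0, k[-1]^(-alpha / 2)) # zero out DC
  x <- Re(fft(sp * scale, inverse = TRUE)) / n
  x * (sd / stats::sd(x))
}

# Unit-peak bi-exponential synaptic template sampled at fs (Hz).
# rise/decay in ms; length covers `span` decay time constants.
biexp_template <- function(fs, rise_ms = 1, decay_ms = 5, span = 8) {
  stopifnot(decay_ms > rise_ms, rise_ms > 0)
  t <- seq(0, span * decay_ms / 1000, by = 1 / fs)
  h <- exp(-t / (decay_ms / 1000)) - exp(-t / (rise_ms / 1000))
  h / max(h)
}

# Centered rolling median with shrinking windows at the edges.
roll_median <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(rep(median(x), length(x)))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

# Centered rolling mean (cumsum-based, edge-truncated windows).
roll_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered rolling raw MAD (no consistency factor) with edge truncation.
roll_mad <- function(x, k, constant = 1) {
  k <- max(1L, as.integer(k))
  zoo::rollapply(x, width = k, FUN = function(v) mad(v, constant = constant),
                 partial = TRUE, align = "center")
}

# First index of each maximal run of TRUE values, plus run lengths.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

stop_if_not_prob <- function(p, what = "probability") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
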