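# Spectral estimators: Welch PSD and DPSS multitaper spectrogram.
# No installed package provides these; both follow the textbook
# definitions (Welch 1967; Percival & Walden 1993, ch. 8 for the
# tridiagonal DPSS formulation).

#' Welch power spectral density estimate
#'
#' The signal is cut into overlapping segments, each demeaned, Hamming
#' windowed and Fourier transformed; the one-sided periodograms are
#' averaged and scaled to a density (power per Hz). Segments containing
#' missing values are dropped.
#'
#' @param x numeric signal (may contain `NA` for masked samples)
#' @param fs sampling rate (Hz)
#' @param win_s segment length (s), default 6
#' @param overlap fractional segment overlap, default 0.2
#' @return list with `freq` (Hz) and `psd` (power / Hz)
#' @export
welch_psd <- function(x, fs, win_s = 6, overlap = 0.2) {
  L <- round(win_s * fs)
  stopifnot(L >= 2, L <= length(x), overlap >= 0, overlap < 1)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1)) # Hamming
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf); n_seg <- 0L
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (anyNA(seg)) next
    X <- fft((seg - mean(seg)) * w)
    pxx <- Mod(X[seq_len(nf)])^2 / (fs * U)
    # one-sided: double all bins except DC (and Nyquist for even L)
    pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
    if (L %% 2L == 1L) pxx[nf] <- 2 * pxx[nf]
    acc <- acc + pxx; n_seg <- n_seg + 1L
  }
  if (n_seg == 0L) return(list(freq = (seq_len(nf) - 1) * fs / L,
                               psd = rep(NA_real_, nf)))
  list(freq = (seq_len(nf) - 1) * fs / L, psd = acc / n_seg)
}

#' Integrated band power from a Welch PSD
#'
#' @param psd result of [welch_psd()]
#' @param band `c(f_lo, f_hi)` in Hz
#' @return integral of the density over the band (rectangle rule)
#' @export
band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[sel]) * df
}

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem; returns an n x k matrix of unit-norm tapers. Cached per
# (n, nw, k) because the spectrogram calls this repeatedly.
.dpss_cache <- new.env(parent = emptyenv())
dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t <- seq_len(n) - 1
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (n - t[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: each taper's mean (or first lobe) positive
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) < 1e-12) s <- v[which.max(abs(v[, j])), j]
    if (s < 0) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper power estimate using `n_tapers` DPSS tapers
#' (time-bandwidth product chosen to admit them, NW = 2 for the default 3
#' tapers). With the default 1-s window and 80 % overlap the time step is
#' 0.2 s. Power is scaled as a one-sided density averaged over tapers.
#'
#' @param x numeric signal at `fs` Hz (may contain `NA`)
#' @param fs sampling rate (Hz)
#' @param win_s window length (s), default 1
#' @param n_tapers number of DPSS tapers, default 3
#' @param overlap fractional window overlap, default 0.8
#' @param f_range `c(f_lo, f_hi)` of frequencies to keep (Hz), default
#'   `c(3, 100)`
#' @param nw time-bandwidth product, default 2
#' @return list with `time` (window centers, s), `freq` (Hz), `power`
#'   (freq x time matrix; `NA` columns for windows touching masked data)
#'   and `step` (s)
#' @export
mt_spectrogram <- function(x, fs, win_s = 1, n_tapers = 3, overlap = 0.8,
                           f_range = c(3, 100), nw = 2) {
  if (f_range[2] > fs / 2) stop("f_range exceeds the Nyquist frequency")
  L <- round(win_s * fs)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  tapers <- dpss_tapers(L, nw, n_tapers)
  freq <- (seq_len(floor(L / 2) + 1L) - 1) * fs / L
  fsel <- which(freq >= f_range[1] & freq <= f_range[2])
  pow <- matrix(NA_real_, length(fsel), length(starts))
  block <- 3000L
  for (b0 in seq(1L, length(starts), by = block)) {
    bi <- b0:min(length(starts), b0 + block - 1L)
    segs <- vapply(starts[bi], function(s) x[s:(s + L - 1L)],
                   numeric(L))
    ok <- !apply(segs, 2L, anyNA)
    if (!any(ok)) next
    acc <- matrix(0, length(fsel), sum(ok))
    for (j in seq_len(n_tapers)) {
      X <- mvfft(segs[, ok, drop = FALSE] * tapers[, j])
      acc <- acc + 2 * Mod(X[fsel, , drop = FALSE])^2 / fs
    }
    pow[, bi[ok]] <- acc / n_tapers
  }
  list(time = (starts - 1L + L / 2) / fs, freq = freq[fsel], power = pow,
       step = step / fs)
}

# Band-summed power time series from a spectrogram (power integrated over
# the band rows, rectangle rule).
spectrogram_bandpower <- function(sg, band) {
  df <- sg$freq[2] - sg$freq[1]
  sel <- sg$freq >= band[1] & sg$freq <= band[2]
  colSums(sg$power[sel, , drop = FALSE]) * df
}
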