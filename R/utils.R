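# Internal helpers: seeded evaluation, interval algebra on half-open
# [start, end) intervals in UNIX seconds, and spectral estimation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the
#' caller's RNG state afterwards, so seeded package functions never
#' perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a sub-seed below 2^31 from a base seed and a
# stream index, so per-session / per-fold randomness is reproducible.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147480000) + 1
  as.integer((s * 48271 + 7919 * as.double(k)) %% 2147483647)
}

# ---- interval algebra ------------------------------------------------------

iv <- function(start = numeric(0), end = numeric(0)) {
  stopifnot(length(start) == length(end))
  keep <- end > start
  data.frame(start = as.numeric(start[keep]), end = as.numeric(end[keep]))
}

iv_normalize <- function(x) {
  if (nrow(x) == 0) return(iv())
  x <- x[order(x$start, x$end), , drop = FALSE]
  out_s <- x$start[1]; out_e <- x$end[1]
  res_s <- numeric(0); res_e <- numeric(0)
  if (nrow(x) > 1) {
    for (i in 2:nrow(x)) {
      if (x$start[i] <= out_e) {
        out_e <- max(out_e, x$end[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- x$start[i]; out_e <- x$end[i]
      }
    }
  }
  iv(c(res_s, out_s), c(res_e, out_e))
}

iv_intersect <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(iv())
  s <- numeric(0); e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start); hi <- pmin(a$end[i], b$end)
    ok <- hi > lo
    s <- c(s, lo[ok]); e <- c(e, hi[ok])
  }
  iv_normalize(iv(s, e))
}

iv_diff <- function(a, b) {
  a <- iv_normalize(a); b <- iv_normalize(b)
  if (nrow(a) == 0) return(iv())
  if (nrow(b) == 0) return(a)
  s <- numeric(0); e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    cur_s <- a$start[i]; cur_e <- a$end[i]
    cuts <- b[b$end > cur_s & b$start < cur_e, , drop = FALSE]
    pos <- cur_s
    if (nrow(cuts) > 0) {
      for (j in seq_len(nrow(cuts))) {
        if (cuts$start[j] > pos) { s <- c(s, pos); e <- c(e, cuts$start[j]) }
        pos <- max(pos, cuts$end[j])
      }
    }
    if (pos < cur_e) { s <- c(s, pos); e <- c(e, cur_e) }
  }
  iv(s, e)
}

iv_duration <- function(x) if (nrow(x) == 0) 0 else sum(x$end - x$start)

# TRUE if [start, end) is wholly contained in one interval of x
iv_contains <- function(x, start, end) {
  any(x$start <= start & x$end >= end)
}

# ---- spectral estimation ---------------------------------------------------

#' Welch power spectral density
#'
#' One-sided Welch periodogram with Hann-windowed segments and 50%
#' overlap. Segments are mean-removed before windowing. Conventions are
#' fixed (64-s segments by default) so feature values are reproducible
#' across platforms.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param seg_sec segment length in seconds (truncated to the signal
#'   length when the signal is shorter).
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @keywords internal
welch_psd <- function(x, fs, seg_sec = 64, overlap = 0.5) {
  n <- length(x)
  L <- min(n, max(8, round(seg_sec * fs)))
  step <- max(1L, as.integer(floor(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  U <- sum(w^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  P <- acc / length(starts)
  half <- seq_len(floor(L / 2) + 1L)
  psd <- P[half]
  # fold negative frequencies into the one-sided estimate
  if (L %% 2 == 0) {
    if (length(half) > 2) psd[2:(length(half) - 1L)] <- 2 * psd[2:(length(half) - 1L)]
  } else {
    if (length(half) > 1) psd[2:length(half)] <- 2 * psd[2:length(half)]
  }
  freq <- (half - 1L) * fs / L
  list(freq = freq, psd = psd)
}

# Integrated band power over [lo, hi) from a PSD estimate.
band_power <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq < hi
  if (!any(sel)) return(0)
  df <- if (length(spec$freq) > 1) spec$freq[2] - spec$freq[1] else 1
  sum(spec$psd[sel]) * df
}

# Normalized Shannon spectral entropy in [0, 1] over a band; 0 for
# degenerate (zero-power) spectra by convention.
spectral_entropy <- function(spec, lo, hi) {
  sel <- spec$freq >= lo & spec$freq < hi
  p <- spec$psd[sel]
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0 || sum(sel) < 2) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(sum(sel))
}

# Least-squares slope of x against time in seconds given sampling rate.
ls_slope <- function(x, rate) {
  n <- length(x)
  if (n < 2) return(0)
  t <- (seq_len(n) - 1) / rate
  vt <- stats::var(t)
  if (vt == 0) return(0)
  stats::cov(t, x) / vt
}

safe_skew <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) return(0)
  e1071::skewness(x)
}

safe_kurt <- function(x) {
  if (length(x) < 4 || stats::sd(x) == 0) return(0)
  e1071::kurtosis(x)
}
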