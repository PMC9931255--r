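#' @keywords internal
"_PACKAGE"

## Shared numerical helpers: spectral estimation, truncated normal draws,
## peak picking. All deterministic; randomness only via the caller's RNG state.

#' Welch averaged-periodogram power spectral density
#'
#' One-sided PSD estimate of a real series using Hann-windowed segments with
#' 50\% overlap. Segments shorter than the full series are averaged; a series
#' shorter than one segment is estimated from a single full-length periodogram.
#'
#' @param x numeric vector (mean is removed per segment).
#' @param fs sampling rate in Hz.
#' @param seg_s segment length in seconds (default 10).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz, excludes DC) and `psd` (units of x^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 10, overlap = 0.5) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  if (n < 8) stop("series too short for spectral estimation")
  L <- min(n, max(8L, round(seg_s * fs)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  U <- sum(w^2)
  nf <- floor(L / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- (Mod(X[2:(nf + 1L)])^2) / (fs * U)
    ## one-sided scaling: double all bins except Nyquist when L even
    p <- 2 * p
    if (L %% 2 == 0) p[nf] <- p[nf] / 2
    acc <- acc + p
  }
  list(freq = (1:nf) * fs / L, psd = acc / length(starts))
}

#' Band power from a PSD
#'
#' Integrates a `welch_psd` estimate over `[f_lo, f_hi]` by the rectangle rule.
#' @param spec list from [welch_psd()].
#' @param f_lo,f_hi band edges in Hz.
#' @return power in units of x^2.
#' @export
band_power <- function(spec, f_lo, f_hi) {
  sel <- spec$freq >= f_lo & spec$freq <= f_hi
  df <- spec$freq[2] - spec$freq[1]
  sum(spec$psd[sel]) * df
}

## Truncated normal draws by inverse-CDF; sd = 0 degenerates to the mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

## Local maxima with a minimum separation (in samples). Candidates are strict
## local maxima; when two fall within `min_dist`, the larger wins and ties go
## to the earliest sample.
find_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ## greedy by height, earliest-first on ties
  ord <- order(-x[cand], cand)
  keep <- logical(length(cand))
  taken <- integer(0)
  for (i in ord) {
    p <- cand[i]
    if (!length(taken) || all(abs(taken - p) >= min_dist)) {
      keep[i] <- TRUE
      taken <- c(taken, p)
    }
  }
  sort(cand[keep])
}

## Filter-step accounting: every removal step logs (n_before, n_removed,
## n_after) and the identity n_before - n_removed = n_after holds by
## construction.
filter_log_entry <- function(stage, n_before, n_removed) {
  data.frame(stage = stage, n_before = n_before, n_removed = n_removed,
             n_after = n_before - n_removed, stringsAsFactors = FALSE)
}

## Deterministic child seeds derived from a master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + as.numeric(k) * 7919
  as.integer(s %% 2147483647)
}
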