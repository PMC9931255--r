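## Per-bout gait parameters.
##
## Temporal parameters come from the detected strides; signal-level measures
## come from the chest/thigh acceleration: RMS of the mean-removed chest AP
## channel, PSD-weighted spectral spread of the chest ML channel, the
## thigh/chest sample-entropy ratio (long bouts), and the largest Lyapunov
## exponent of the chest AP and ML channels (laboratory one-minute bouts).
## Feature arity is a function of bout class only: 8 for short/medium/all-home
## bouts, 9 for long (adds the entropy ratio), 11 in the lab (adds both
## Lyapunov exponents).

#' Temporal gait parameters from detected strides
#'
#' Arithmetic means of stride, stance and swing time and duty factor, plus
#' coefficients of variation (sample SD with n-1 divided by the mean) of
#' stride time and duty factor.
#'
#' @param strides data.frame from [detect_gait_events()] with >= 2 rows.
#' @return named list of `stride_time_mean_s, stance_time_mean_s,
#'   swing_time_mean_s, stride_time_cv, duty_factor_mean, duty_factor_cv`.
#' @export
temporal_parameters <- function(strides) {
  if (nrow(strides) < 2) stop("insufficient strides: need at least 2")
  cv <- function(x) stats::sd(x) / mean(x)
  list(stride_time_mean_s = mean(strides$stride_s),
       stance_time_mean_s = mean(strides$stance_s),
       swing_time_mean_s = mean(strides$swing_s),
       stride_time_cv = cv(strides$stride_s),
       duty_factor_mean = mean(strides$duty_factor),
       duty_factor_cv = cv(strides$duty_factor))
}

#' RMS of the mean-removed chest AP acceleration
#'
#' @param x numeric vector, chest AP channel in g.
#' @param fs unused; kept for a uniform feature signature.
#' @return RMS in g.
#' @export
rms_ap <- function(x, fs = NULL) {
  x <- x - mean(x)
  sqrt(mean(x^2))
}

#' Medial-lateral frequency dispersion
#'
#' PSD-weighted standard deviation of frequency,
#' `sqrt(sum(P(f) (f - fbar)^2) / sum(P(f)))` with `fbar` the PSD-weighted
#' mean, computed from the Welch PSD of the mean-removed ML channel over
#' `(0, fs/2]`. Invariant to amplitude scaling.
#'
#' @param x numeric vector, chest ML channel.
#' @param fs sampling rate in Hz.
#' @return dispersion in Hz.
#' @export
freq_dispersion_ml <- function(x, fs) {
  if (length(x) < 4 * fs - 0.5) stop("bout shorter than 4 s")
  if (all(abs(x - mean(x)) < 1e-15)) {
    stop("undefined dispersion: signal has no power")
  }
  sp <- welch_psd(x - mean(x), fs, seg_s = 10, overlap = 0.5)
  w <- sp$psd / sum(sp$psd)
  fbar <- sum(w * sp$freq)
  sqrt(sum(w * (sp$freq - fbar)^2))
}

#' Sample entropy
#'
#' SampEn(m, r): negative log of the conditional probability that sequences
#' matching for `m` points (Chebyshev distance < `r`) also match for `m + 1`,
#' excluding self-matches.
#'
#' @param x numeric series.
#' @param m embedding length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy (non-negative; `Inf` when no m+1 matches exist).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n <= m + 1) stop("series too short for sample entropy")
  ## both template lengths use the same N - m template population
  nB <- count_template_pairs(x, m, r, n_templates = n - m)
  nA <- count_template_pairs(x, m + 1, r, n_templates = n - m)
  if (nB == 0) stop("undefined entropy: no template matches at length m")
  if (nA == 0) return(Inf)
  -log(nA / nB)
}

## Pairwise (i < j) template matches of length mm within Chebyshev distance r.
count_template_pairs <- function(x, mm, r, n_templates) {
  cols <- lapply(seq_len(mm), function(k) x[k:(k + n_templates - 1L)])
  total <- 0
  for (i in seq_len(n_templates - 1L)) {
    idx <- (i + 1L):n_templates
    d <- abs(cols[[1]][idx] - cols[[1]][i])
    if (mm > 1) for (k in 2:mm) d <- pmax(d, abs(cols[[k]][idx] - cols[[k]][i]))
    total <- total + sum(d < r)
  }
  total
}

#' Thigh/chest sample-entropy ratio
#'
#' Sample entropy (m = 2, r = 0.2 x SD of each series) of the mean-removed
#' resultant (vector-magnitude) acceleration, thigh divided by chest.
#' Defined for long bouts (>= 32 s).
#'
#' @param thigh_bout,chest_bout 3 x T matrices of equal length.
#' @param m,r_frac sample-entropy parameters.
#' @return unitless ratio (> 0).
#' @export
entropy_ratio <- function(thigh_bout, chest_bout, m = 2, r_frac = 0.2) {
  stopifnot(ncol(thigh_bout) == ncol(chest_bout))
  res <- function(sig) {
    v <- sqrt(colSums(sig^2))
    v - mean(v)
  }
  xt <- res(thigh_bout); xc <- res(chest_bout)
  et <- sample_entropy(xt, m, r_frac * stats::sd(xt))
  ec <- sample_entropy(xc, m, r_frac * stats::sd(xc))
  if (ec == 0) stop("undefined ratio: chest entropy is zero")
  et / ec
}

#' Largest Lyapunov exponent (divergence-curve method)
#'
#' Delay embedding (dimension 5; delay at the first minimum of the
#' autocorrelation, capped at a quarter stride period), nearest neighbours
#' outside a one-stride Theiler window, mean log divergence over
#' 0-0.5 stride periods, slope by least squares, reported per second.
#'
#' @param x numeric vector (one chest channel), mean-removed internally.
#' @param fs sampling rate in Hz.
#' @param stride_freq stride frequency in Hz (from [estimate_cadence()]).
#' @param dim embedding dimension (default 5).
#' @return exponent in 1/s.
#' @export
max_lyapunov <- function(x, fs, stride_freq, dim = 5) {
  x <- x - mean(x)
  Tstr <- fs / stride_freq
  ac <- stats::acf(x, lag.max = ceiling(Tstr), plot = FALSE)$acf[-1]
  lag_min <- which(diff(ac) > 0)[1]  # first local minimum of the acf
  if (is.na(lag_min)) lag_min <- ceiling(Tstr / 4)
  delay <- min(lag_min, max(1L, floor(Tstr / 4)))
  N <- length(x) - (dim - 1) * delay
  K <- round(0.5 * Tstr)
  if (N - K < 2 * dim) stop("estimation error: too few embedded points")
  emb <- sapply(0:(dim - 1), function(k) x[(1 + k * delay):(N + k * delay)])
  theiler <- round(Tstr)
  usable <- N - K
  D <- as.matrix(stats::dist(emb[seq_len(usable), , drop = FALSE]))
  idx <- seq_len(usable)
  off <- abs(outer(idx, idx, "-"))
  D[off <= theiler] <- Inf
  D[D == 0] <- Inf                         # skip exactly coincident states
  nn <- apply(D, 1, which.min)
  valid <- is.finite(D[cbind(idx, nn)])
  if (sum(valid) < dim) stop("estimation error: no valid neighbours")
  div <- vapply(0:K, function(k) {
    i <- idx[valid]; j <- nn[valid]
    d <- sqrt(rowSums((emb[i + k, , drop = FALSE] - emb[j + k, , drop = FALSE])^2))
    mean(log(d + 1e-12))
  }, 1)
  stats::coef(stats::lm(div ~ I(0:K)))[2] * fs
}

#' Extract the per-bout feature vector
#'
#' Dispatches the parameter computations and enforces feature arity by bout
#' class: 8 features for short/medium home bouts, 9 for long home bouts
#' (adds the entropy ratio), 11 for laboratory bouts (adds the AP and ML
#' Lyapunov exponents). Partial vectors are never emitted: any component
#' failure propagates.
#'
#' @param bout a `walking_bout` with element `strides` (filtered data.frame).
#' @param context `"home"` or `"lab"`.
#' @param config an `msf_config`.
#' @param lyapunov_home also compute Lyapunov exponents on home bouts longer
#'   than 60 s (exploratory; off by default, consistent with the 8/9/11
#'   feature counts).
#' @return one-row data.frame of parameters plus `subject_id, bout_id,
#'   duration_class, context`.
#' @export
extract_bout_parameters <- function(bout, context = "home",
                                    config = load_config(),
                                    lyapunov_home = FALSE) {
  stopifnot(context %in% c("home", "lab"))
  tp <- temporal_parameters(bout$strides)
  cls <- if (context == "lab") "lab" else
    categorize_bout_duration(bout$duration_s, config)
  out <- data.frame(subject_id = bout$subject_id %||% NA_character_,
                    bout_id = bout$bout_id, duration_class = cls,
                    context = context, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tp))
  out$rms_ap_g <- rms_ap(bout$chest["ap", ])
  out$freqd_ml_hz <- freq_dispersion_ml(bout$chest["ml", ], bout$fs)
  long_enough <- context == "lab" || cls == "long"
  out$entropy_ratio <- if (long_enough) {
    entropy_ratio(bout$thigh, bout$chest)
  } else NA_real_
  want_ly <- context == "lab" || (lyapunov_home && bout$duration_s > 60)
  if (want_ly && bout$duration_s <= 60) {
    stop("Lyapunov exponents require bouts longer than 60 s")
  }
  if (want_ly) {
    cad <- estimate_cadence(bout$thigh, bout$fs)
    if (inherits(cad, "cadence_not_found")) stop("cadence needed for Lyapunov")
    out$ly_ap_per_s <- max_lyapunov(bout$chest["ap", ], bout$fs, cad$stride_freq)
    out$ly_ml_per_s <- max_lyapunov(bout$chest["ml", ], bout$fs, cad$stride_freq)
  } else {
    out$ly_ap_per_s <- NA_real_
    out$ly_ml_per_s <- NA_real_
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Feature-set column names per duration selector (8/9/11 arity).
feature_columns <- function(selector) {
  base <- c("stride_time_mean_s", "stance_time_mean_s", "swing_time_mean_s",
            "stride_time_cv", "duty_factor_mean", "duty_factor_cv",
            "rms_ap_g", "freqd_ml_hz")
  switch(selector,
         short = base, medium = base, all_home = base,
         long = c(base, "entropy_ratio"),
         lab = c(base, "entropy_ratio", "ly_ap_per_s", "ly_ml_per_s"),
         stop("unknown selector: ", selector))
}
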