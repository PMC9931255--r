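## Foot-contact / foot-off detection within walking bouts.
##
## Cadence (stride and step frequency) is estimated from the Welch power
## spectral density of the mean-removed thigh AP channel; a zero-phase filter
## bank centred on those frequencies yields a stride-band signal (one cycle
## per stride) and a step-band signal carrying the event transients. Foot
## contacts are the prominent step-band peaks gated to one per stride-band
## cycle; the foot off is the subsequent step-band trough within the same
## cycle. Strides are assembled from consecutive contacts.

#' Estimate stride and step frequency from the thigh PSD
#'
#' Averaged periodogram (10-s Hann segments, 50\% overlap; the full bout when
#' shorter) of the mean-removed thigh AP channel. The stride frequency is the
#' dominant peak in 0.4-1.2 Hz; the step frequency is the dominant peak within
#' 20\% of twice the stride frequency. A bout whose peak does not rise above
#' the broadband noise floor is flagged invalid.
#'
#' @param thigh_bout 3 x T matrix (rows v/ml/ap) or a `walking_bout`.
#' @param fs sampling rate in Hz.
#' @param stride_range stride-frequency search band in Hz.
#' @param min_peak_ratio minimum ratio of the peak to the median in-band PSD.
#' @return list of class `cadence_estimate` with `stride_freq`, `step_freq`,
#'   `psd_peak_power`, or an object of class `cadence_not_found`.
#' @export
estimate_cadence <- function(thigh_bout, fs, stride_range = c(0.4, 1.2),
                             min_peak_ratio = 10) {
  x <- event_channel(thigh_bout)
  if (length(x) < 4 * fs - 0.5) stop("bout shorter than 4 s")
  x <- x - mean(x)
  sp <- welch_psd(x, fs, seg_s = 10, overlap = 0.5)
  wide <- sp$freq >= 0.3 & sp$freq <= 5
  floor_p <- stats::median(sp$psd[wide])
  sel <- sp$freq >= stride_range[1] & sp$freq <= stride_range[2]
  pk <- which.max(sp$psd[sel])
  f_stride <- sp$freq[sel][pk]
  p_stride <- sp$psd[sel][pk]
  if (!is.finite(p_stride) || p_stride < min_peak_ratio * floor_p) {
    return(structure(list(reason = "no cadence peak above noise floor"),
                     class = "cadence_not_found"))
  }
  sel2 <- sp$freq >= 0.8 * 2 * f_stride & sp$freq <= 1.2 * 2 * f_stride
  if (!any(sel2)) {
    return(structure(list(reason = "no step-frequency band available"),
                     class = "cadence_not_found"))
  }
  pk2 <- which.max(sp$psd[sel2])
  structure(list(stride_freq = f_stride, step_freq = sp$freq[sel2][pk2],
                 psd_peak_power = p_stride),
            class = "cadence_estimate")
}

event_channel <- function(bout) {
  if (inherits(bout, "walking_bout")) bout <- bout$thigh
  if (is.matrix(bout)) bout["ap", ] else bout
}

#' Zero-phase filter bank at the stride and step frequencies
#'
#' Two 4th-order Butterworth band-passes (two pole pairs each) applied
#' forward-backward, centred on the estimated stride and step frequencies
#' with +/-20\% relative bandwidth. Output lengths equal the input length.
#'
#' @param thigh_bout 3 x T matrix or `walking_bout`.
#' @param cadence a `cadence_estimate`.
#' @param fs sampling rate in Hz.
#' @param rel_bw relative half-bandwidth (default 0.2).
#' @return list with `stride_band` and `step_band` numeric vectors.
#' @export
bank_filter <- function(thigh_bout, cadence, fs, rel_bw = 0.2) {
  stopifnot(inherits(cadence, "cadence_estimate"))
  x <- event_channel(thigh_bout)
  x <- x - mean(x)
  bp <- function(f0) {
    lo <- f0 * (1 - rel_bw); hi <- f0 * (1 + rel_bw)
    if (lo <= 0 || hi >= fs / 2) stop("filter error: band edges outside (0, fs/2)")
    flt <- signal::butter(2, c(lo, hi) / (fs / 2), "pass")
    signal::filtfilt(flt, x)
  }
  list(stride_band = bp(cadence$stride_freq), step_band = bp(cadence$step_freq))
}

#' Detect foot-contact and foot-off events in a bout
#'
#' The stride-band output of the filter bank gates the signal into one cycle
#' per stride; within each gated window the foot contact is the apex of the
#' zero-phase transient-band (2.5-10 Hz) event signal, where the heel-strike
#' impact concentrates, and the foot off is the subsequent event-signal
#' trough before the next contact. Ties in peak prominence break to the
#' earliest sample.
#'
#' @param thigh_bout 3 x T matrix or `walking_bout`.
#' @param fs sampling rate in Hz.
#' @param cadence optional precomputed `cadence_estimate`.
#' @param transient_band event-localization band in Hz.
#' @return data.frame of strides with `fc_s, fo_s, next_fc_s, stride_s,
#'   stance_s, swing_s, duty_factor` (empty with attribute `removed = TRUE`
#'   when cadence fails or fewer than two strides are found). Times are
#'   relative to the bout start.
#' @export
detect_gait_events <- function(thigh_bout, fs, cadence = NULL,
                               transient_band = c(2.5, 10)) {
  if (is.null(cadence)) cadence <- estimate_cadence(thigh_bout, fs)
  empty <- function() {
    out <- data.frame(fc_s = numeric(0), fo_s = numeric(0),
                      next_fc_s = numeric(0), stride_s = numeric(0),
                      stance_s = numeric(0), swing_s = numeric(0),
                      duty_factor = numeric(0))
    attr(out, "removed") <- TRUE
    out
  }
  if (inherits(cadence, "cadence_not_found")) return(empty())
  bands <- bank_filter(thigh_bout, cadence, fs)
  x <- event_channel(thigh_bout)
  x <- x - mean(x)
  hi_edge <- min(transient_band[2], 0.45 * fs)
  flt <- signal::butter(2, c(transient_band[1], hi_edge) / (fs / 2), "pass")
  ev <- signal::filtfilt(flt, x)
  Tstr <- fs / cadence$stride_freq          # stride period in samples
  ## one stride-band peak per cycle anchors the gating
  anchors <- find_peaks(bands$stride_band, min_dist = round(0.6 * Tstr))
  if (length(anchors) < 2) return(empty())
  n <- length(ev)
  fc <- integer(0)
  for (a in anchors) {
    lo <- max(1L, a - round(0.35 * Tstr)); hi <- min(n, a + round(0.35 * Tstr))
    seg <- ev[lo:hi]
    fc <- c(fc, lo + which.max(seg) - 1L)   # which.max: earliest on ties
  }
  fc <- sort(unique(fc))
  ## enforce one contact per cycle: drop contacts closer than half a stride,
  ## keeping the stronger (earliest on ties)
  if (length(fc) > 1) {
    keep <- rep(TRUE, length(fc))
    for (i in 2:length(fc)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (fc[i] - fc[prev] < 0.5 * Tstr) {
        if (ev[fc[i]] > ev[fc[prev]]) {
          keep[prev] <- FALSE
        } else keep[i] <- FALSE
      }
    }
    fc <- fc[keep]
  }
  if (length(fc) < 3) return(empty())      # need >= 2 strides
  strides <- list()
  for (i in seq_len(length(fc) - 1L)) {
    c0 <- fc[i]; c1 <- fc[i + 1L]
    lo <- c0 + max(1L, round(0.15 * (c1 - c0)))
    hi <- c1 - max(1L, round(0.05 * (c1 - c0)))
    if (hi <= lo) next
    seg <- ev[lo:hi]
    fo <- lo + which.min(seg) - 1L
    strides[[length(strides) + 1]] <- data.frame(
      fc_s = (c0 - 1L) / fs, fo_s = (fo - 1L) / fs, next_fc_s = (c1 - 1L) / fs)
  }
  if (length(strides) < 2) return(empty())
  out <- do.call(rbind, strides)
  out$stride_s <- out$next_fc_s - out$fc_s
  out$stance_s <- out$fo_s - out$fc_s
  out$swing_s <- out$next_fc_s - out$fo_s
  out$duty_factor <- out$stance_s / out$stride_s
  attr(out, "removed") <- FALSE
  out
}

#' Filter bouts and strides by validity ranges
#'
#' Removes bouts with fewer than two detected strides; removes individual
#' strides whose stride time, duty factor, stance or swing time fall outside
#' the configured physiological ranges; re-checks the two-stride minimum after
#' stride-level removal. Every step logs `(n_before, n_removed, n_after)`.
#'
#' @param bout_strides list; each element has `$strides` (data.frame from
#'   [detect_gait_events()]) plus any bout metadata.
#' @param validity_ranges list as in [load_config()]`$validity_ranges`.
#' @return list with `retained` (the surviving elements, strides filtered),
#'   `log` (data.frame of filter steps), `n_strides_removed`.
#' @export
filter_valid <- function(bout_strides,
                         validity_ranges = load_config()$validity_ranges) {
  vr <- validity_ranges
  n0 <- length(bout_strides)
  has2 <- vapply(bout_strides, function(b) nrow(b$strides) >= 2, TRUE)
  log1 <- filter_log_entry("bouts_lt_2_strides", n0, sum(!has2))
  kept <- bout_strides[has2]
  n_str_before <- sum(vapply(kept, function(b) nrow(b$strides), 1L))
  n_removed_strides <- 0L
  kept <- lapply(kept, function(b) {
    s <- b$strides
    ok <- s$stride_s >= vr$stride_time[1] & s$stride_s <= vr$stride_time[2] &
      s$duty_factor >= vr$duty_factor[1] & s$duty_factor <= vr$duty_factor[2] &
      s$stance_s >= vr$stance_min_s & s$swing_s >= vr$swing_min_s
    n_removed_strides <<- n_removed_strides + sum(!ok)
    b$strides <- s[ok, , drop = FALSE]
    b
  })
  log2 <- filter_log_entry("strides_out_of_range", n_str_before,
                           n_removed_strides)
  has2b <- vapply(kept, function(b) nrow(b$strides) >= 2, TRUE)
  log3 <- filter_log_entry("bouts_lt_2_strides_post", length(kept), sum(!has2b))
  list(retained = kept[has2b], log = rbind(log1, log2, log3),
       n_strides_removed = n_removed_strides)
}
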