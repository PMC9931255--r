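# Shared fixtures: small profiles and bouts built in code.

FS <- 31.25

ref_profile <- function(stride_time_mean = 1.16, stride_time_cv = 0.05,
                        duty_factor_mean = 0.62, ap_amplitude = 0.14,
                        ml_bandwidth = 0.6) {
  list(stride_time_mean = stride_time_mean, stride_time_cv = stride_time_cv,
       duty_factor_mean = duty_factor_mean, ap_amplitude = ap_amplitude,
       ml_bandwidth = ml_bandwidth)
}

# A walking_bout built directly from a synthetic segment (bypasses the window
# classifier): signals trimmed to a whole number of 4-s windows, detected
# strides attached.
segment_bout <- function(profile = ref_profile(), n_strides = 20, seed = 1,
                         subject_id = "S001", bout_id = 1L, detect = TRUE) {
  seg <- synth_walking_segment(profile, n_strides, FS, seed)
  nwin <- floor(ncol(seg$thigh) / (4 * FS))
  n <- round(nwin * 4 * FS)
  b <- structure(list(bout_id = bout_id, start_s = 0, end_s = nwin * 4,
                      duration_s = nwin * 4,
                      chest = seg$chest[, seq_len(n), drop = FALSE],
                      thigh = seg$thigh[, seq_len(n), drop = FALSE],
                      fs = FS, subject_id = subject_id),
                 class = "walking_bout")
  if (detect) b$strides <- detect_gait_events(b$thigh, FS)
  b$truth <- seg
  b
}

# Match each detected foot contact to the nearest ground-truth contact and
# return per-event absolute errors (seconds) plus matched stride-time errors.
event_errors <- function(detected, truth) {
  fc_true <- truth$events$fc_s
  m <- vapply(detected$fc_s, function(t) which.min(abs(fc_true - t)), 1L)
  fc_err <- abs(detected$fc_s - fc_true[m])
  ok <- m <= length(truth$stride_s)
  stride_err <- abs(detected$stride_s[ok] - truth$stride_s[m[ok]])
  list(fc_err = fc_err, stride_err = stride_err)
}

# Brute-force AUC by pair enumeration (independent oracle).
auc_bruteforce <- function(scores, labels) {
  pos <- which(labels %in% c("faller", 1, TRUE))
  neg <- setdiff(seq_along(labels), pos)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p-value by full enumeration of rank assignments
# (independent oracle; no ties assumed).
wilcox_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(na + nb, na)
  ws <- colSums(matrix(seq_len(na + nb)[combos], nrow = na))
  mu <- na * (na + nb + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
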