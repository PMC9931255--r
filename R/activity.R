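## Gait/non-gait window classification and walking-bout assembly.
##
## Free-living recordings are tiled into non-overlapping 4-second windows of
## stacked chest+thigh acceleration (6 channels). Windows are labelled gait or
## non-gait either by a trained recurrent classifier (a single BiLSTM layer
## with dropout, full-scale default 215 units / 40% dropout) or by a
## deterministic spectral detector; maximal runs of gait windows become
## walking bouts, so one non-gait window separates bouts and bout durations
## are multiples of the window length.

#' Tile paired recordings into non-overlapping windows
#'
#' @param chest,thigh `accel_recording`s at the same rate (lengths trimmed to
#'   the shorter).
#' @param window_s window length in seconds (default 4).
#' @return list with `inputs` (list of 6 x n matrices, chest channels 1-3 then
#'   thigh 4-6), `n_windows`, `window_s`, `fs`.
#' @export
window_signal <- function(chest, thigh, window_s = 4) {
  stopifnot(inherits(chest, "accel_recording"), inherits(thigh, "accel_recording"))
  if (abs(chest$fs - thigh$fs) > 1e-9) stop("recordings must share a sampling rate")
  fs <- chest$fs
  n <- min(ncol(chest$data), ncol(thigh$data))
  wlen <- round(window_s * fs)
  nw <- n %/% wlen
  if (nw == 0) {
    warning("recording shorter than one window")
    return(list(inputs = list(), n_windows = 0L, window_s = window_s, fs = fs))
  }
  inputs <- lapply(seq_len(nw), function(i) {
    rng <- ((i - 1L) * wlen + 1L):(i * wlen)
    rbind(chest$data[, rng], thigh$data[, rng])
  })
  list(inputs = inputs, n_windows = nw, window_s = window_s, fs = fs)
}

#' Deterministic spectral gait detector
#'
#' Labels a window gait when the band power of the mean-removed thigh AP
#' channel in the 0.4-3 Hz gait band exceeds a calibrated threshold. Scores
#' are `p / (p + threshold)` so they lie in `[0, 1]` with 0.5 at the
#' threshold. Provides a no-training path behind the same contract as the
#' learned classifier.
#'
#' @param windows output of [window_signal()].
#' @param threshold gait-band power threshold in g^2 (default 0.02).
#' @param band gait band in Hz.
#' @return data.frame with `label` (`"gait"`/`"non_gait"`) and `score`.
#' @export
spectral_gait_detector <- function(windows, threshold = 0.02,
                                   band = c(0.4, 3)) {
  fs <- windows$fs
  res <- lapply(windows$inputs, function(w) {
    x <- w[6, ] - mean(w[6, ])  # thigh AP
    sp <- welch_psd(x, fs, seg_s = windows$window_s, overlap = 0)
    p <- band_power(sp, band[1], band[2])
    data.frame(label = if (p > threshold) "gait" else "non_gait",
               score = p / (p + threshold), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Train the recurrent window classifier
#'
#' A single bidirectional LSTM layer followed by dropout and a dense softmax
#' head, trained with Adam; inputs are z-normalized per channel with
#' training-set statistics (stored in the model). Defaults follow the
#' full-scale architecture (215 hidden units, 40\% dropout); reduced sizes are
#' appropriate for tests and small synthetic sets.
#'
#' @param inputs list of 6 x n window matrices.
#' @param labels per-window labels, `"gait"`/`"non_gait"` (or any 2-level
#'   vector whose second sorted level is the positive class `"gait"` is
#'   detected automatically when present).
#' @param units BiLSTM hidden units.
#' @param dropout dropout fraction.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param holdout fraction of windows held out for the reported accuracy.
#' @param lr,batch_size optimizer settings.
#' @return object of class `window_classifier` with `$holdout_accuracy`.
#' @export
train_window_classifier <- function(inputs, labels, units = 215, dropout = 0.40,
                                    epochs = 30, seed = 1, holdout = 0.2,
                                    lr = 0.01, batch_size = 32) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("training error: single-class training set")
  pos <- if ("gait" %in% labels) "gait" else sort(unique(labels))[2]
  y <- as.integer(labels == pos)
  set.seed(seed)
  n <- length(inputs)
  n_hold <- max(1L, round(holdout * n))
  hold <- sample.int(n, n_hold)
  tr <- setdiff(seq_len(n), hold)
  if (length(unique(y[tr])) < 2) stop("training error: single-class training split")
  spec <- lstm_spec(list(list(type = "bilstm", units = units, dropout = dropout)),
                    epochs = epochs, lr = lr, batch_size = batch_size)
  model <- lstm_train(inputs[tr], y[tr], spec, seed = seed)
  sc <- lstm_scores(model, inputs[hold])
  acc <- mean((sc > 0.5) == (y[hold] == 1))
  structure(list(model = model, positive = pos,
                 holdout_accuracy = acc, n_train = length(tr)),
            class = "window_classifier")
}

#' Classify windows with a trained model or the spectral fallback
#'
#' @param classifier a `window_classifier`, or the string `"spectral"` to use
#'   [spectral_gait_detector()].
#' @param windows output of [window_signal()].
#' @param ... passed to the spectral detector.
#' @return data.frame with `label` and `score` (probability of gait).
#' @export
classify_windows <- function(classifier, windows, ...) {
  if (identical(classifier, "spectral")) {
    return(spectral_gait_detector(windows, ...))
  }
  stopifnot(inherits(classifier, "window_classifier"))
  if (length(windows$inputs) == 0) {
    return(data.frame(label = character(0), score = numeric(0)))
  }
  if (nrow(windows$inputs[[1]]) != classifier$model$n_channels) {
    stop("input error: window channel count does not match training shape")
  }
  sc <- lstm_scores(classifier$model, windows$inputs)
  data.frame(label = ifelse(sc > 0.5, "gait", "non_gait"), score = sc,
             stringsAsFactors = FALSE)
}

#' Assemble walking bouts from sequential window labels
#'
#' Maximal runs of gait windows become bouts; a single non-gait window splits
#' bouts. Bout durations are run length times the window length.
#'
#' @param window_labels character (`"gait"`/`"non_gait"`) or 0/1 vector in
#'   temporal order.
#' @param window_s window length in seconds.
#' @return data.frame with `bout_id, start_s, end_s, duration_s, n_windows`.
#' @export
assemble_bouts <- function(window_labels, window_s = 4) {
  if (is.character(window_labels) || is.factor(window_labels)) {
    g <- as.character(window_labels) == "gait"
  } else {
    g <- window_labels == 1
  }
  if (!length(g) || !any(g)) {
    return(data.frame(bout_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_windows = integer(0)))
  }
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(bout_id = seq_along(sel),
             start_s = (starts[sel] - 1L) * window_s,
             end_s = ends[sel] * window_s,
             duration_s = r$lengths[sel] * window_s,
             n_windows = r$lengths[sel])
}

#' Extract per-bout signal views from paired recordings
#'
#' @param bouts data.frame from [assemble_bouts()].
#' @param chest,thigh `accel_recording`s.
#' @return list of `walking_bout` objects: `bout_id`, `start_s`, `end_s`,
#'   `duration_s`, `chest`, `thigh` (3 x T slices), `fs`.
#' @export
bout_views <- function(bouts, chest, thigh) {
  fs <- chest$fs
  lapply(seq_len(nrow(bouts)), function(i) {
    rng <- (round(bouts$start_s[i] * fs) + 1L):min(round(bouts$end_s[i] * fs),
                                                   ncol(chest$data))
    structure(list(bout_id = bouts$bout_id[i], start_s = bouts$start_s[i],
                   end_s = bouts$end_s[i], duration_s = bouts$duration_s[i],
                   chest = chest$data[, rng, drop = FALSE],
                   thigh = thigh$data[, rng, drop = FALSE], fs = fs,
                   subject_id = chest$subject_id),
              class = "walking_bout")
  })
}
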