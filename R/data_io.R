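## File formats, run configuration and logging.
##
## All on-disk artifacts are plain CSV/JSON with fixed column orders so that
## pipeline outputs are diff-able and byte-stable under a fixed seed.

#' Construct an acceleration recording
#'
#' @param subject_id subject identifier.
#' @param location sensor site, `"chest"` or `"thigh_right"`.
#' @param fs sampling rate in Hz.
#' @param data 3 x T numeric matrix in g, axis rows `[vertical, ML, AP]`.
#' @return object of class `accel_recording`.
#' @export
accel_recording <- function(subject_id, location, fs, data) {
  stopifnot(location %in% c("chest", "thigh_right"), fs > 0,
            is.matrix(data), nrow(data) == 3, ncol(data) > 0,
            all(is.finite(data)))
  rownames(data) <- c("v", "ml", "ap")
  structure(list(subject_id = subject_id, location = location, fs = fs,
                 data = data), class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s, %s, %.4g Hz, %.1f s\n",
              x$subject_id, x$location, x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

time_fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Write one sensor's time series to CSV
#'
#' Columns `time_s, acc_v_g, acc_ml_g, acc_ap_g` with a mandatory header row;
#' values at full double precision so a write/read round trip is lossless.
#' @param rec an `accel_recording`.
#' @param path output file.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  n <- ncol(rec$data)
  df <- data.frame(time_s = time_fmt((seq_len(n) - 1) / rec$fs),
                   acc_v_g = time_fmt(rec$data["v", ]),
                   acc_ml_g = time_fmt(rec$data["ml", ]),
                   acc_ap_g = time_fmt(rec$data["ap", ]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sensor time series from CSV
#'
#' Validates the schema, timestamp monotonicity and sampling uniformity
#' (maximum jitter below half a sample period), and infers the sampling rate
#' from the median timestamp increment.
#'
#' @param path CSV file with columns `time_s, acc_v_g, acc_ml_g, acc_ap_g`.
#' @param subject_id,location metadata attached to the recording.
#' @return an `accel_recording`.
#' @export
read_recording <- function(path, subject_id = NA_character_,
                           location = "chest") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "acc_v_g", "acc_ml_g", "acc_ap_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error: missing column(s) ",
                         paste(miss, collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("data error: time stamps not strictly increasing")
  per <- stats::median(dt)
  if (max(abs(dt - per)) > per / 2) {
    stop("data error: sampling not uniform (jitter exceeds half a period)")
  }
  fs <- round(1 / per, 6)  # snap text-roundoff jitter in the inferred rate
  accel_recording(subject_id, location, fs,
                  rbind(v = df$acc_v_g, ml = df$acc_ml_g, ap = df$acc_ap_g))
}

#' Pipeline configuration with study defaults
#'
#' Defaults: 4-s windows, 31.25 Hz target rate, duration classes short <= 8 s /
#' medium 12-28 s / long >= 32 s, alpha = 0.05, 95\% PCA variance retention,
#' and stride validity ranges (stride time 0.5-3 s, duty factor 0.45-0.85,
#' stance/swing >= 0.1 s).
#'
#' @param path optional YAML or JSON file whose entries override the defaults.
#' @param ... named overrides applied after the file.
#' @return object of class `msf_config`.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- list(
    window_s = 4,
    fs_target = 31.25,
    duration_class_bounds = list(short_max_s = 8, medium_min_s = 12,
                                 medium_max_s = 28, long_min_s = 32),
    alpha = 0.05,
    pca_variance = 0.95,
    seed = 1L,
    validity_ranges = list(stride_time = c(0.5, 3.0),
                           duty_factor = c(0.45, 0.85),
                           stance_min_s = 0.1, swing_min_s = 0.1)
  )
  if (!is.null(path)) {
    ov <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
    if (!is.null(ov)) cfg <- utils::modifyList(cfg, ov)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  validate_config(cfg)
  structure(cfg, class = "msf_config")
}

validate_config <- function(cfg) {
  b <- cfg$duration_class_bounds
  if (!(b$short_max_s < b$medium_min_s)) {
    stop("configuration error: short_max_s must be < medium_min_s")
  }
  if (!(b$medium_min_s <= b$medium_max_s)) {
    stop("configuration error: medium_min_s must be <= medium_max_s")
  }
  if (!(b$medium_max_s < b$long_min_s)) {
    stop("configuration error: medium_max_s must be < long_min_s")
  }
  if (!(cfg$pca_variance > 0 && cfg$pca_variance <= 1)) {
    stop("configuration error: pca_variance must be in (0, 1]")
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("configuration error: alpha must be in (0, 1)")
  }
  invisible(cfg)
}

#' Save a configuration to YAML
#' @param config an `msf_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits, per subject, two sensor CSVs and one JSON annotation file
#' (`{"bouts": [{"start_s":..., "end_s":..., "class":..., "events": [[fc, fo], ...]}, ...],
#' "windows": [0/1, ...]}`), plus a cohort table CSV.
#'
#' @param cohort an `msf_cohort`.
#' @param recordings named list (by subject id) of outputs of
#'   [generate_subject_recording()].
#' @param out_dir output directory (created if needed).
#' @return data.frame manifest (subject_id, kind, path).
#' @export
write_dataset <- function(cohort, recordings, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("I/O error: ", out_dir, " not writable")
  man <- list()
  add <- function(sid, kind, path) {
    man[[length(man) + 1]] <<- data.frame(subject_id = sid, kind = kind,
                                          path = path, stringsAsFactors = FALSE)
  }
  for (sid in names(recordings)) {
    rec <- recordings[[sid]]
    pc <- file.path(out_dir, paste0(sid, "_chest.csv"))
    pt <- file.path(out_dir, paste0(sid, "_thigh.csv"))
    write_recording(rec$chest, pc); add(sid, "sensor_chest", pc)
    write_recording(rec$thigh, pt); add(sid, "sensor_thigh", pt)
    tr <- rec$truth
    bouts <- lapply(seq_len(nrow(tr$bouts)), function(i) {
      ev <- tr$events[[i]]
      np <- length(ev$fc_s)
      list(start_s = tr$bouts$start_s[i], end_s = tr$bouts$end_s[i],
           class = tr$bouts$class[i],
           events = lapply(seq_len(np), function(j) c(ev$fc_s[j], ev$fo_s[j])))
    })
    pj <- file.path(out_dir, paste0(sid, "_annotations.json"))
    jsonlite::write_json(list(bouts = bouts, windows = tr$window_labels),
                         pj, auto_unbox = TRUE, digits = NA)
    add(sid, "annotations", pj)
  }
  pcoh <- file.path(out_dir, "cohort.csv")
  utils::write.csv(as.data.frame(cohort), pcoh, row.names = FALSE)
  man[[length(man) + 1]] <- data.frame(subject_id = NA, kind = "cohort",
                                       path = pcoh, stringsAsFactors = FALSE)
  do.call(rbind, man)
}

#' Read a JSON annotation file
#' @param path annotation JSON written by [write_dataset()].
#' @return list with `bouts` data.frame, `events` per bout, `window_labels`.
#' @export
read_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nb <- length(j$bouts)
  bouts <- do.call(rbind, lapply(seq_len(nb), function(i) {
    b <- j$bouts[[i]]
    data.frame(bout_id = i, start_s = b$start_s, end_s = b$end_s,
               class = b$class, stringsAsFactors = FALSE)
  }))
  events <- lapply(j$bouts, function(b) {
    fc <- vapply(b$events, function(e) as.numeric(e[[1]]), 1)
    fo <- vapply(b$events, function(e) as.numeric(e[[2]]), 1)
    list(fc_s = fc, fo_s = fo)
  })
  list(bouts = bouts, events = events,
       window_labels = as.integer(unlist(j$windows)))
}

#' Resample a recording to a target rate
#'
#' Linear interpolation onto the target grid; used to bring 250 Hz laboratory
#' recordings onto the free-living 31.25 Hz rate so both contexts share one
#' feature-extraction path.
#' @param rec an `accel_recording`.
#' @param fs_target target rate in Hz.
#' @return an `accel_recording` at `fs_target`.
#' @export
resample_recording <- function(rec, fs_target) {
  if (abs(rec$fs - fs_target) < 1e-9) return(rec)
  n <- ncol(rec$data)
  t_old <- (seq_len(n) - 1) / rec$fs
  t_new <- seq(0, t_old[n], by = 1 / fs_target)
  d <- vapply(1:3, function(r) stats::approx(t_old, rec$data[r, ], t_new)$y,
              numeric(length(t_new)))
  accel_recording(rec$subject_id, rec$location, fs_target, t(d))
}
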