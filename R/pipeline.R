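## End-to-end pipeline driver: activity classification -> bout assembly ->
## stride events -> gait parameters -> group analysis -> fall-risk
## classification, with plain CSV/JSON artifacts at every stage.

#' Reference free-living bout counts
#'
#' Published per-category walking-bout counts from the 38-subject free-living
#' study the pipeline emulates: 9,135 short, 4,840 medium and 1,122 long
#' bouts (15,097 in total). Used to recompute category shares.
#' @return data.frame with `class` and `n_bouts`.
#' @export
msfall_study_counts <- function() {
  data.frame(class = c("short", "medium", "long"),
             n_bouts = c(9135L, 4840L, 1122L),
             stringsAsFactors = FALSE)
}

pipeline_stages <- c("classify", "bouts", "events", "features", "analyze",
                     "classify_risk")

#' Run the free-living gait pipeline
#'
#' Executes the requested stages in order over a dataset directory produced
#' by [write_dataset()] (sensor CSVs + cohort table). Stage artifacts are
#' written to `out_dir`; a stage whose upstream artifact is neither requested
#' nor already on disk raises a dependency error. Window classification uses
#' the deterministic spectral detector unless a trained classifier is given.
#' Every filter step logs its counts.
#'
#' @param config an `msf_config`.
#' @param input_dir dataset directory.
#' @param out_dir artifact directory (created).
#' @param stages subset of
#'   `c("classify","bouts","events","features","analyze","classify_risk")`.
#' @param classifier `"spectral"` or a `window_classifier`.
#' @param families model families for the fall-risk stage.
#' @return invisible list of artifact paths.
#' @export
run_pipeline <- function(config, input_dir, out_dir,
                         stages = pipeline_stages, classifier = "spectral",
                         families = c("LR", "KNN")) {
  stopifnot(all(stages %in% pipeline_stages))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(out_dir, name)
  need <- function(stage, file) {
    if (!(stage %in% stages) && !file.exists(art(file))) {
      stop("dependency error: stage requires '", stage,
           "' output (", file, ") which is neither requested nor on disk")
    }
  }
  cohort_path <- file.path(input_dir, "cohort.csv")
  if (!file.exists(cohort_path)) stop("cohort.csv not found in ", input_dir)
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  subjects <- cohort$subject_id
  read_pair <- function(sid) {
    ch <- read_recording(file.path(input_dir, paste0(sid, "_chest.csv")), sid, "chest")
    th <- read_recording(file.path(input_dir, paste0(sid, "_thigh.csv")), sid, "thigh_right")
    if (abs(ch$fs - config$fs_target) > 1e-6) ch <- resample_recording(ch, config$fs_target)
    if (abs(th$fs - config$fs_target) > 1e-6) th <- resample_recording(th, config$fs_target)
    list(chest = ch, thigh = th)
  }
  paths <- list()
  if ("classify" %in% stages || "bouts" %in% stages) {
    win_rows <- list()
    for (sid in subjects) {
      pr <- read_pair(sid)
      w <- window_signal(pr$chest, pr$thigh, config$window_s)
      cl <- classify_windows(classifier, w)
      win_rows[[sid]] <- data.frame(subject_id = sid,
                                    window = seq_len(nrow(cl)),
                                    label = cl$label,
                                    score = round(cl$score, 6),
                                    stringsAsFactors = FALSE)
    }
    windows_tbl <- do.call(rbind, win_rows)
    rownames(windows_tbl) <- NULL
    utils::write.csv(windows_tbl, art("windows.csv"), row.names = FALSE)
    paths$windows <- art("windows.csv")
    message(sprintf("classify: %d windows, %d gait",
                    nrow(windows_tbl), sum(windows_tbl$label == "gait")))
  }
  if ("bouts" %in% stages) {
    need("classify", "windows.csv")
    windows_tbl <- utils::read.csv(art("windows.csv"), stringsAsFactors = FALSE)
    bout_rows <- list()
    for (sid in subjects) {
      lb <- windows_tbl$label[windows_tbl$subject_id == sid]
      b <- assemble_bouts(lb, config$window_s)
      if (nrow(b)) bout_rows[[sid]] <- cbind(subject_id = sid, b)
    }
    bouts_tbl <- do.call(rbind, bout_rows)
    rownames(bouts_tbl) <- NULL
    utils::write.csv(bouts_tbl, art("bouts.csv"), row.names = FALSE)
    paths$bouts <- art("bouts.csv")
    message(sprintf("bouts: %d assembled", nrow(bouts_tbl)))
  }
  if ("events" %in% stages) {
    need("bouts", "bouts.csv")
    bouts_tbl <- utils::read.csv(art("bouts.csv"), stringsAsFactors = FALSE)
    all_bouts <- list()
    for (sid in subjects) {
      pr <- read_pair(sid)
      bs <- bouts_tbl[bouts_tbl$subject_id == sid, , drop = FALSE]
      if (!nrow(bs)) next
      views <- bout_views(bs, pr$chest, pr$thigh)
      for (v in views) {
        v$strides <- detect_gait_events(v$thigh, v$fs)
        all_bouts[[length(all_bouts) + 1]] <- v
      }
    }
    flt <- filter_valid(all_bouts, config$validity_ranges)
    utils::write.csv(flt$log, art("filter_log.csv"), row.names = FALSE)
    stride_rows <- lapply(flt$retained, function(b) {
      s <- b$strides
      data.frame(subject_id = b$subject_id, bout_id = b$bout_id,
                 stride_idx = seq_len(nrow(s)),
                 fc_s = round(b$start_s + s$fc_s, 6),
                 fo_s = round(b$start_s + s$fo_s, 6),
                 stride_s = round(s$stride_s, 6),
                 stance_s = round(s$stance_s, 6),
                 swing_s = round(s$swing_s, 6),
                 duty_factor = round(s$duty_factor, 6),
                 stringsAsFactors = FALSE)
    })
    strides_tbl <- do.call(rbind, stride_rows)
    utils::write.csv(strides_tbl, art("strides.csv"), row.names = FALSE)
    paths$strides <- art("strides.csv")
    for (i in seq_len(nrow(flt$log))) {
      message(sprintf("events filter [%s]: before %d removed %d after %d",
                      flt$log$stage[i], flt$log$n_before[i],
                      flt$log$n_removed[i], flt$log$n_after[i]))
    }
  }
  if ("features" %in% stages) {
    need("events", "strides.csv")
    strides_tbl <- utils::read.csv(art("strides.csv"), stringsAsFactors = FALSE)
    need("bouts", "bouts.csv")
    bouts_tbl <- utils::read.csv(art("bouts.csv"), stringsAsFactors = FALSE)
    param_rows <- list()
    for (sid in subjects) {
      pr <- read_pair(sid)
      bs <- bouts_tbl[bouts_tbl$subject_id == sid, , drop = FALSE]
      views <- bout_views(bs, pr$chest, pr$thigh)
      for (v in views) {
        s <- strides_tbl[strides_tbl$subject_id == sid &
                           strides_tbl$bout_id == v$bout_id, , drop = FALSE]
        if (nrow(s) < 2) next
        v$strides <- data.frame(fc_s = s$fc_s - v$start_s,
                                fo_s = s$fo_s - v$start_s,
                                stride_s = s$stride_s, stance_s = s$stance_s,
                                swing_s = s$swing_s, duty_factor = s$duty_factor)
        v$strides$next_fc_s <- v$strides$fc_s + v$strides$stride_s
        p <- tryCatch(extract_bout_parameters(v, "home", config),
                      error = function(e) NULL)
        if (!is.null(p)) param_rows[[length(param_rows) + 1]] <- p
      }
    }
    params_tbl <- do.call(rbind, param_rows)
    num <- vapply(params_tbl, is.numeric, TRUE)
    params_tbl[num] <- lapply(params_tbl[num], function(x) round(x, 8))
    utils::write.csv(params_tbl, art("parameters.csv"), row.names = FALSE)
    paths$parameters <- art("parameters.csv")
    message(sprintf("features: %d bout parameter vectors", nrow(params_tbl)))
  }
  if ("analyze" %in% stages) {
    need("features", "parameters.csv")
    params_tbl <- utils::read.csv(art("parameters.csv"), stringsAsFactors = FALSE)
    suite <- suppressWarnings(comparison_suite(params_tbl, cohort, config))
    for (nm in names(suite)) {
      if (!is.null(suite[[nm]]) && nrow(suite[[nm]])) {
        tb <- suite[[nm]]
        tb$p_value <- round(tb$p_value, 8)
        tb$median_a <- round(tb$median_a, 8)
        tb$median_b <- round(tb$median_b, 8)
        utils::write.csv(tb, art(paste0("comparison_", nm, ".csv")),
                         row.names = FALSE)
        paths[[paste0("comparison_", nm)]] <- art(paste0("comparison_", nm, ".csv"))
      }
    }
  }
  if ("classify_risk" %in% stages) {
    need("features", "parameters.csv")
    params_tbl <- utils::read.csv(art("parameters.csv"), stringsAsFactors = FALSE)
    reports <- list()
    for (sel in c("short", "medium", "long", "all_home")) {
      fm <- tryCatch(build_feature_matrix(params_tbl, cohort, sel),
                     error = function(e) NULL)
      if (is.null(fm) || length(unique(fm$subject_id)) < 3 ||
          length(unique(fm$label)) < 2) next
      for (fam in families) {
        out <- tryCatch(
          loso_feature_classifiers(fm, fam, config, seed = config$seed),
          error = function(e) NULL)
        if (is.null(out)) next
        reports[[length(reports) + 1]] <- list(
          feature_set = sel, model = fam,
          auc_per_input = out$auc_per_input,
          auc_subject_median = out$auc_subject_median)
      }
    }
    jsonlite::write_json(reports, art("classifier_report.json"),
                         auto_unbox = TRUE, digits = 8)
    paths$classifier_report <- art("classifier_report.json")
  }
  invisible(paths)
}
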