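## Duration stratification, per-subject summaries, group comparisons, and
## k-nearest-neighbour survey imputation.
##
## Walking bouts are stratified as short (<= 8 s), medium (12-28 s) or long
## (>= 32 s); the 4-s window quantization makes the classification total.
## Group differences use two-sided Wilcoxon rank-sum tests at alpha = 0.05
## with no multiplicity correction (a Benjamini-Hochberg option exists, off by
## default).

#' Classify a bout duration
#'
#' @param duration_s bout duration(s) in seconds, multiples of the window
#'   length.
#' @param config an `msf_config` providing the class bounds.
#' @return character vector in `{"short", "medium", "long"}`.
#' @export
categorize_bout_duration <- function(duration_s, config = load_config()) {
  b <- config$duration_class_bounds
  w <- config$window_s
  stopifnot(all(duration_s > 0))
  if (any(abs(duration_s / w - round(duration_s / w)) > 1e-9)) {
    stop("quantization error: durations must be multiples of the window length")
  }
  out <- ifelse(duration_s <= b$short_max_s, "short",
                ifelse(duration_s >= b$medium_min_s & duration_s <= b$medium_max_s,
                       "medium",
                       ifelse(duration_s >= b$long_min_s, "long", NA)))
  if (anyNA(out)) {
    stop("quantization error: duration falls between class bounds")
  }
  out
}

summary_stat_names <- c("mean", "median", "max", "min", "sd", "p5", "p95")

#' Summarize a subject's bout parameters within a duration class
#'
#' Seven statistics per parameter: mean, median, max, min, SD, 5th and 95th
#' percentile (linear interpolation between order statistics). A single bout
#' yields mean = median = max = min = p5 = p95 = value and SD = 0.
#'
#' @param param_table bout parameter table (rows = bouts).
#' @param subject_id subject to summarize.
#' @param duration_class one of `"short"`, `"medium"`, `"long"`.
#' @param parameters parameter columns to summarize (default: the feature
#'   columns available for the class).
#' @return one-row data.frame with columns `<stat>_<parameter>`, or `NULL`
#'   when the subject has no bout in the class (missing-summary marker).
#' @export
summarize_subject <- function(param_table, subject_id, duration_class,
                              parameters = NULL) {
  sel <- param_table$subject_id == subject_id &
    param_table$duration_class == duration_class
  rows <- param_table[sel, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  if (is.null(parameters)) {
    parameters <- intersect(feature_columns(
      if (duration_class %in% c("short", "medium", "long")) duration_class else "all_home"),
      names(rows))
  }
  out <- list(subject_id = subject_id, duration_class = duration_class,
              n_bouts = nrow(rows))
  for (p in parameters) {
    v <- rows[[p]]
    v <- v[is.finite(v)]
    if (!length(v)) next
    q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
    st <- c(mean = mean(v), median = stats::median(v), max = max(v),
            min = min(v), sd = if (length(v) > 1) stats::sd(v) else 0,
            p5 = q[1], p95 = q[2])
    for (s in names(st)) out[[paste0(s, "_", p)]] <- unname(st[s])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Summaries for every subject and duration class
#' @inheritParams summarize_subject
#' @param subjects subject ids (default: all in the table).
#' @param classes duration classes (default short/medium/long).
#' @return data.frame, one row per subject x class with at least one bout.
#' @export
summarize_subjects <- function(param_table, subjects = NULL,
                               classes = c("short", "medium", "long")) {
  if (is.null(subjects)) subjects <- unique(param_table$subject_id)
  rows <- list()
  for (s in subjects) for (cl in classes) {
    r <- summarize_subject(param_table, s, cl)
    if (!is.null(r)) rows[[length(rows) + 1]] <- r
  }
  if (!length(rows)) return(NULL)
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(nms, names(r))] <- NA; r[nms] })
  do.call(rbind, rows)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact enumeration when the smaller sample has at most 8 observations and
#' there are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise. Reports both medians alongside the p-value.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @param alpha significance level.
#' @param feature,comparison_id optional labels carried into the output.
#' @return one-row data.frame: `comparison_id, feature, median_a, median_b,
#'   p_value, significant`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, alpha = 0.05,
                              feature = NA_character_,
                              comparison_id = NA_character_) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (length(unique(c(sample_a, sample_b))) == 1L) {
    p <- 1
  } else {
    ties <- any(duplicated(c(sample_a, sample_b)))
    exact <- !ties && min(length(sample_a), length(sample_b)) <= 8
    p <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  }
  data.frame(comparison_id = comparison_id, feature = feature,
             median_a = stats::median(sample_a),
             median_b = stats::median(sample_b),
             p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Group comparison suites over the bout parameter table
#'
#' Produces analogues of the three reported comparison layouts:
#' \describe{
#'   \item{duration}{duration vs duration on pooled bout-level values
#'     (short/medium, short/long, medium/long) over the 8 common features.}
#'   \item{context}{lab vs each home duration and vs all home bouts,
#'     bout-level; the lab-vs-long comparison adds the entropy ratio and both
#'     Lyapunov exponents when available.}
#'   \item{fall_risk}{faller vs non-faller on per-subject summary statistics
#'     (7 statistics per feature) within each duration class.}
#' }
#' All tests are two-sided Wilcoxon rank-sum at `config$alpha` with no
#' multiplicity correction; `p_adjust = "BH"` applies Benjamini-Hochberg
#' within each suite instead.
#'
#' @param param_table bout parameter table (home context rows, and lab rows
#'   with `context == "lab"` if present).
#' @param cohort an `msf_cohort` (needed for the fall-risk suite).
#' @param config an `msf_config`.
#' @param unit unit of analysis for the fall-risk suite:
#'   `"subject_summary"` (default) or `"bout"`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return named list of data.frames `duration`, `context`, `fall_risk`.
#' @export
comparison_suite <- function(param_table, cohort = NULL,
                             config = load_config(),
                             unit = c("subject_summary", "bout"),
                             p_adjust = "none") {
  unit <- match.arg(unit)
  alpha <- config$alpha
  home <- param_table[param_table$context == "home", , drop = FALSE]
  lab <- param_table[param_table$context == "lab", , drop = FALSE]
  base_feats <- feature_columns("all_home")
  finish <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    if (p_adjust == "BH") {
      df$p_value <- stats::p.adjust(df$p_value, "BH")
      df$significant <- df$p_value < alpha
    }
    rownames(df) <- NULL
    df
  }
  ## (i) duration vs duration, pooled bout-level
  dur_tbl <- list()
  pairs <- list(c("short", "medium"), c("short", "long"), c("medium", "long"))
  for (pr in pairs) {
    a <- home[home$duration_class == pr[1], , drop = FALSE]
    b <- home[home$duration_class == pr[2], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) next
    for (f in base_feats) {
      va <- a[[f]][is.finite(a[[f]])]; vb <- b[[f]][is.finite(b[[f]])]
      if (!length(va) || !length(vb)) next
      dur_tbl[[length(dur_tbl) + 1]] <-
        wilcoxon_rank_sum(va, vb, alpha, f, paste(pr, collapse = "_vs_"))
    }
  }
  duration <- finish(if (length(dur_tbl)) do.call(rbind, dur_tbl) else NULL)
  ## (ii) lab vs home per duration and all-home
  context <- NULL
  if (nrow(lab)) {
    ctx_tbl <- list()
    groups <- list(short = "short", medium = "medium", long = "long",
                   all_home = c("short", "medium", "long"))
    for (g in names(groups)) {
      b <- home[home$duration_class %in% groups[[g]], , drop = FALSE]
      if (!nrow(b)) next
      feats <- if (g == "long") {
        intersect(feature_columns("lab"), names(param_table))
      } else base_feats
      for (f in feats) {
        va <- lab[[f]][is.finite(lab[[f]])]
        vb <- b[[f]][is.finite(b[[f]])]
        if (!length(va) || !length(vb)) next
        ctx_tbl[[length(ctx_tbl) + 1]] <-
          wilcoxon_rank_sum(va, vb, alpha, f, paste0("lab_vs_", g))
      }
    }
    context <- finish(if (length(ctx_tbl)) do.call(rbind, ctx_tbl) else NULL)
  } else {
    warning("no lab context rows; context comparison table skipped")
  }
  ## (iii) fallers vs non-fallers
  fall <- NULL
  if (!is.null(cohort)) {
    lab_map <- stats::setNames(cohort$fall_label, cohort$subject_id)
    fr_tbl <- list()
    for (cl in c("short", "medium", "long")) {
      if (unit == "subject_summary") {
        sm <- summarize_subjects(home, classes = cl)
        if (is.null(sm)) next
        grp <- lab_map[sm$subject_id]
        stat_cols <- setdiff(names(sm), c("subject_id", "duration_class", "n_bouts"))
        for (sc in stat_cols) {
          va <- sm[[sc]][grp == "faller"]; vb <- sm[[sc]][grp == "non_faller"]
          va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
          if (length(va) < 2 || length(vb) < 2) next
          fr_tbl[[length(fr_tbl) + 1]] <-
            wilcoxon_rank_sum(va, vb, alpha, sc, paste0("fall_", cl))
        }
      } else {
        b <- home[home$duration_class == cl, , drop = FALSE]
        grp <- lab_map[b$subject_id]
        for (f in base_feats) {
          va <- b[[f]][grp == "faller"]; vb <- b[[f]][grp == "non_faller"]
          va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
          if (length(va) < 2 || length(vb) < 2) next
          fr_tbl[[length(fr_tbl) + 1]] <-
            wilcoxon_rank_sum(va, vb, alpha, f, paste0("fall_", cl))
        }
      }
    }
    fall <- finish(if (length(fr_tbl)) do.call(rbind, fr_tbl) else NULL)
  }
  list(duration = duration, context = context, fall_risk = fall)
}

#' k-nearest-neighbour imputation of missing survey entries
#'
#' A missing survey value is replaced by the mean of that field over the k
#' nearest complete rows, with distance computed as Euclidean distance on the
#' z-scored remaining survey fields.
#'
#' @param cohort an `msf_cohort` (or data.frame) with survey columns
#'   `abc, edss, mfis, msws, nsi`, possibly containing `NA`.
#' @param k neighbours (default 3).
#' @return the completed table.
#' @export
impute_surveys_knn <- function(cohort, k = 3) {
  fields <- c("abc", "edss", "mfis", "msws", "nsi")
  x <- as.data.frame(cohort)[, fields]
  complete <- stats::complete.cases(x)
  if (sum(complete) < k) stop("imputation error: fewer than k complete rows")
  mu <- colMeans(x[complete, ])
  sdv <- vapply(x[complete, ], stats::sd, 1)
  sdv[sdv < 1e-12] <- 1
  z <- sweep(sweep(as.matrix(x), 2, mu), 2, sdv, "/")
  out <- cohort
  for (i in which(!complete)) {
    miss <- which(is.na(x[i, ]))
    use <- setdiff(seq_along(fields), miss)
    d <- sqrt(rowSums((z[complete, use, drop = FALSE] -
                         matrix(z[i, use], sum(complete), length(use),
                                byrow = TRUE))^2))
    nn <- order(d)[seq_len(k)]
    donors <- which(complete)[nn]
    for (mj in miss) out[[fields[mj]]][i] <- mean(x[donors, mj])
  }
  out
}
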