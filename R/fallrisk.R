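## Leave-one-subject-out fall-risk classification.
##
## Feature-based path: per LOSO fold, z-score then PCA are fitted on training
## rows only, components are kept up to >= 95% cumulative variance, and one of
## five classifier families (logistic regression, SVM, decision tree, k-NN,
## ensemble of trees) scores the held-out subject's bouts. Sequence path:
## 6-channel raw-acceleration inputs built from k consecutive strides feed a
## recurrent network under a modified LOSO with a rotating validation subject;
## per-subject median decision scores give the aggregated AUC. The positive
## class is "faller" throughout.

#' Area under the ROC curve (rank form)
#'
#' The Mann-Whitney pair statistic: the fraction of (positive, negative)
#' score pairs correctly ordered, ties counted one half.
#'
#' @param scores numeric decision scores (higher = more faller-like).
#' @param labels binary labels; `"faller"`/1/TRUE is positive.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  pos <- labels %in% c("faller", 1, TRUE)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a per-bout feature matrix for one duration selector
#'
#' @param param_table bout parameter table.
#' @param cohort an `msf_cohort` supplying fall labels.
#' @param selector one of `"short"`, `"medium"`, `"long"`, `"all_home"`,
#'   `"lab"`; column arity is 8/8/9/8/11 accordingly.
#' @return list of class `feature_matrix`: `x` (matrix), `subject_id`,
#'   `label`, `selector`, `n_dropped` (rows dropped for missing features).
#' @export
build_feature_matrix <- function(param_table, cohort, selector) {
  cols <- feature_columns(selector)
  rows <- switch(selector,
                 lab = param_table[param_table$context == "lab", , drop = FALSE],
                 all_home = param_table[param_table$context == "home", , drop = FALSE],
                 param_table[param_table$context == "home" &
                               param_table$duration_class == selector, , drop = FALSE])
  if (!nrow(rows)) stop("empty feature matrix for selector ", selector)
  x <- as.matrix(rows[, cols, drop = FALSE])
  ok <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  n_dropped <- sum(!ok)
  if (n_dropped) message(sprintf("dropping %d rows with missing features", n_dropped))
  rows <- rows[ok, , drop = FALSE]; x <- x[ok, , drop = FALSE]
  if (!nrow(x)) stop("empty feature matrix for selector ", selector)
  lab_map <- stats::setNames(cohort$fall_label, cohort$subject_id)
  structure(list(x = x, subject_id = rows$subject_id,
                 label = unname(lab_map[rows$subject_id]),
                 selector = selector, n_dropped = n_dropped),
            class = "feature_matrix")
}

## z-score + PCA fitted on training rows only; keeps the smallest component
## count reaching >= var_target cumulative variance.
fit_reducer <- function(x_train, var_target = 0.95) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  z <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= var_target)[1]
  list(mu = mu, sd = sdv, rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
       ncomp = ncomp, explained = cum[ncomp])
}

apply_reducer <- function(red, x) {
  z <- sweep(sweep(x, 2, red$mu), 2, red$sd, "/")
  z %*% red$rotation
}

## Hyperparameter draws per family for the seeded random search.
draw_hyper <- function(family, n) {
  switch(family,
         LR = replicate(n, list(), simplify = FALSE),
         SVM = lapply(seq_len(n), function(i)
           list(cost = 10^stats::runif(1, -2, 2),
                gamma = 10^stats::runif(1, -3, 1))),
         tree = lapply(seq_len(n), function(i)
           list(cp = 10^stats::runif(1, -4, -1),
                minsplit = sample(5:30, 1))),
         KNN = lapply(seq_len(n), function(i) list(k = sample(1:25, 1))),
         ensemble = lapply(seq_len(n), function(i)
           list(ntree = sample(c(100, 200, 300), 1),
                mtry_frac = stats::runif(1, 0.3, 1))))
}

fit_score <- function(family, hyper, x_tr, y_tr, x_te) {
  y_tr <- factor(y_tr, levels = c("non_faller", "faller"))
  df_tr <- data.frame(y = y_tr, x_tr)
  df_te <- data.frame(x_te)
  colnames(df_te) <- colnames(df_tr)[-1]
  switch(family,
         LR = {
           fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
           as.numeric(stats::predict(fit, df_te, type = "response"))
         },
         SVM = {
           fit <- e1071::svm(y ~ ., data = df_tr, probability = TRUE,
                             cost = hyper$cost %||% 1, gamma = hyper$gamma %||% (1 / ncol(x_tr)),
                             kernel = "radial")
           pr <- attr(stats::predict(fit, df_te, probability = TRUE), "probabilities")
           as.numeric(pr[, "faller"])
         },
         tree = {
           fit <- rpart::rpart(y ~ ., data = df_tr, method = "class",
                               control = rpart::rpart.control(
                                 cp = hyper$cp %||% 0.01,
                                 minsplit = hyper$minsplit %||% 20))
           as.numeric(stats::predict(fit, df_te, type = "prob")[, "faller"])
         },
         KNN = {
           k <- min(hyper$k %||% 5, nrow(x_tr))
           pr <- class::knn(x_tr, x_te, y_tr, k = k, prob = TRUE)
           p <- attr(pr, "prob")
           ifelse(pr == "faller", p, 1 - p)
         },
         ensemble = {
           mtry <- max(1, round((hyper$mtry_frac %||% 0.6) * ncol(x_tr)))
           fit <- randomForest::randomForest(x_tr, y_tr,
                                             ntree = hyper$ntree %||% 200,
                                             mtry = min(mtry, ncol(x_tr)))
           as.numeric(stats::predict(fit, x_te, type = "prob")[, "faller"])
         },
         stop("unknown model family: ", family))
}

## Inner tuning split: hold out ~25% of training subjects (>= 1), requiring
## both classes on each side; returns the best hyper by inner AUC.
tune_family <- function(family, x, sid, y, subjects_tr, n_draws, seed) {
  if (n_draws <= 0 || family == "LR") return(list())
  set.seed(seed)
  hypers <- draw_hyper(family, n_draws)
  subj_lab <- vapply(subjects_tr, function(s) y[sid == s][1], "")
  n_hold <- max(1L, round(0.25 * length(subjects_tr)))
  hold <- character(0)
  for (cl in unique(subj_lab)) {
    cand <- subjects_tr[subj_lab == cl]
    hold <- c(hold, sample(cand, max(1L, round(n_hold * length(cand) /
                                                 length(subjects_tr)))))
  }
  inner_tr <- !(sid %in% hold)
  if (length(unique(y[inner_tr])) < 2 || length(unique(y[!inner_tr])) < 2) {
    return(hypers[[1]])
  }
  red <- fit_reducer(x[inner_tr, , drop = FALSE])
  ptr <- apply_reducer(red, x[inner_tr, , drop = FALSE])
  pte <- apply_reducer(red, x[!inner_tr, , drop = FALSE])
  aucs <- vapply(hypers, function(h) {
    sc <- tryCatch(fit_score(family, h, ptr, y[inner_tr], pte),
                   error = function(e) rep(0.5, sum(!inner_tr)))
    compute_auc(sc, y[!inner_tr])
  }, 1)
  hypers[[which.max(aucs)]]
}

#' Feature-based LOSO-CV fall-risk classification
#'
#' Per fold: fit z-score and PCA on the training rows only (keeping the
#' smallest component count explaining >= `config$pca_variance` of variance),
#' tune the family's hyperparameters by seeded random search inside the
#' training subjects, fit, and score the held-out subject's bouts. Held-out
#' scores pooled over folds give the per-input AUC; per-subject median scores
#' give the aggregated AUC.
#'
#' @param fm a `feature_matrix`.
#' @param family `"LR"`, `"SVM"`, `"tree"`, `"KNN"` or `"ensemble"`.
#' @param config an `msf_config`.
#' @param seed integer seed.
#' @param n_draws random-search draws (0 = family defaults).
#' @return list of class `classifier_outcome`: `scores` data.frame
#'   (`subject_id, score, label, fold`), `auc_per_input`,
#'   `auc_subject_median`, `folds`, `family`, `pca_ncomp` per fold.
#' @export
loso_feature_classifiers <- function(fm, family = "LR",
                                     config = load_config(), seed = 1,
                                     n_draws = 8) {
  stopifnot(inherits(fm, "feature_matrix"))
  subjects <- unique(fm$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects for LOSO")
  if (length(unique(fm$label)) < 2) stop("both classes must be present")
  scores <- list(); ncomps <- integer(0)
  for (fi in seq_along(subjects)) {
    s <- subjects[fi]
    te <- fm$subject_id == s
    tr <- !te
    if (length(unique(fm$label[tr])) < 2) {
      warning("fold for subject ", s, " skipped: single-class training set")
      next
    }
    red <- fit_reducer(fm$x[tr, , drop = FALSE], config$pca_variance)
    ncomps <- c(ncomps, red$ncomp)
    hyper <- tune_family(family, fm$x[tr, , drop = FALSE], fm$subject_id[tr],
                         fm$label[tr], setdiff(subjects, s), n_draws,
                         derive_seed(seed, fi))
    ptr <- apply_reducer(red, fm$x[tr, , drop = FALSE])
    pte <- apply_reducer(red, fm$x[te, , drop = FALSE])
    set.seed(derive_seed(seed, 10000 + fi))
    sc <- fit_score(family, hyper, ptr, fm$label[tr], pte)
    scores[[length(scores) + 1]] <- data.frame(
      subject_id = s, score = sc, label = fm$label[te][1], fold = fi,
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, scores)
  med <- stats::aggregate(score ~ subject_id + label, scores, stats::median)
  structure(list(scores = scores,
                 auc_per_input = compute_auc(scores$score, scores$label),
                 auc_subject_median = compute_auc(med$score, med$label),
                 folds = stats::setNames(seq_along(subjects), subjects),
                 family = family, pca_ncomp = ncomps),
            class = "classifier_outcome")
}

#' Build stride-sequence inputs from a bout
#'
#' Slides a window of `k` consecutive strides (step one stride) over the
#' bout's stride sequence; each input is the 6-channel raw acceleration
#' (chest then thigh) from the first of the k contacts to the (k+1)-th
#' contact. Bouts with fewer than k strides contribute nothing. With
#' `include_abc`, the subject's balance-confidence score is appended as a
#' constant seventh channel.
#'
#' @param bout a `walking_bout` with `$strides` and signal views.
#' @param k strides per input (>= 1).
#' @param include_abc append the ABC score channel.
#' @param abc the subject's ABC score (required when `include_abc`).
#' @param step `1` for the sliding window (default) or `k` for disjoint
#'   blocks.
#' @return list of channels x time matrices (possibly empty).
#' @export
build_stride_inputs <- function(bout, k = 4, include_abc = FALSE, abc = NULL,
                                step = 1) {
  stopifnot(k >= 1)
  s <- bout$strides
  n <- nrow(s)
  if (is.null(n) || n < k) return(list())
  fs <- bout$fs
  out <- list()
  for (i in seq(1, n - k + 1, by = step)) {
    a <- round(s$fc_s[i] * fs) + 1L
    b <- round(s$next_fc_s[i + k - 1] * fs)
    b <- min(b, ncol(bout$chest))
    if (b <= a) next
    m <- rbind(bout$chest[, a:b, drop = FALSE], bout$thigh[, a:b, drop = FALSE])
    if (include_abc) {
      if (is.null(abc)) stop("abc score required when include_abc = TRUE")
      m <- rbind(m, abc = rep(abc, ncol(m)))
    }
    out[[length(out) + 1]] <- m
  }
  out
}

#' Train a sequence fall-risk model
#'
#' Thin wrapper over the recurrent engine: z-scores channels with
#' training-set statistics, trains with Adam, returns softmax decision scores
#' via [lstm_scores()]. Reduced architectures (fewer units/epochs) are
#' selected by passing a smaller [lstm_spec()]; the contract is unchanged.
#'
#' @param inputs list of channels x time matrices.
#' @param labels per-input labels (`"faller"`/`"non_faller"`).
#' @param arch an [lstm_spec()] (e.g. [arch_lstm2()], [arch_lstm3()]).
#' @param seed integer seed.
#' @param epochs optional override.
#' @return an `lstm_model`.
#' @export
train_sequence_model <- function(inputs, labels, arch, seed = 1, epochs = NULL) {
  if (length(unique(labels)) < 2) stop("training error: single-class data")
  y <- as.integer(labels == "faller")
  lstm_train(inputs, y, arch, seed = seed, epochs = epochs)
}

#' Modified LOSO sequence classification
#'
#' Per fold the test subject is held out and a validation subject is chosen
#' by fixed rotation (the next subject id cyclically); the remainder train.
#' Train/validation/test subject sets are disjoint in every fold. Held-out
#' scores pooled over folds give `auc_per_input`; per-subject median scores
#' give `auc_subject_median`.
#'
#' @param inputs list of channels x time matrices.
#' @param subject_id per-input subject ids.
#' @param labels per-input labels.
#' @param arch an [lstm_spec()].
#' @param seed integer seed.
#' @param epochs optional override.
#' @return a `classifier_outcome` with an additional `val_auc` per fold.
#' @export
loso_sequence_classification <- function(inputs, subject_id, labels, arch,
                                         seed = 1, epochs = NULL) {
  subjects <- sort(unique(subject_id))
  if (length(subjects) < 3) stop("need at least 3 subjects")
  scores <- list(); val_auc <- numeric(0); fold_map <- list()
  for (fi in seq_along(subjects)) {
    s_test <- subjects[fi]
    s_val <- subjects[(fi %% length(subjects)) + 1]
    tr <- !(subject_id %in% c(s_test, s_val))
    if (length(unique(labels[tr])) < 2) {
      warning("fold for subject ", s_test, " skipped: single-class training set")
      next
    }
    model <- train_sequence_model(inputs[tr], labels[tr], arch,
                                  seed = derive_seed(seed, fi), epochs = epochs)
    vi <- subject_id == s_val
    va <- if (length(unique(labels[vi])) == 2) {
      compute_auc(lstm_scores(model, inputs[vi]), labels[vi])
    } else NA_real_
    val_auc <- c(val_auc, va)
    te <- subject_id == s_test
    sc <- lstm_scores(model, inputs[te])
    scores[[length(scores) + 1]] <- data.frame(
      subject_id = s_test, score = sc, label = labels[te][1], fold = fi,
      stringsAsFactors = FALSE)
    fold_map[[as.character(s_test)]] <- list(test = s_test, validation = s_val,
                                             train = setdiff(subjects, c(s_test, s_val)))
  }
  scores <- do.call(rbind, scores)
  med <- stats::aggregate(score ~ subject_id + label, scores, stats::median)
  structure(list(scores = scores,
                 auc_per_input = compute_auc(scores$score, scores$label),
                 auc_subject_median = compute_auc(med$score, med$label),
                 folds = fold_map, val_auc = val_auc, family = "sequence"),
            class = "classifier_outcome")
}

#' @export
print.classifier_outcome <- function(x, ...) {
  cat(sprintf("<classifier_outcome> %s: AUC per input %.3f, subject-median %.3f (%d folds)\n",
              x$family, x$auc_per_input, x$auc_subject_median,
              length(unique(x$scores$fold))))
  invisible(x)
}
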