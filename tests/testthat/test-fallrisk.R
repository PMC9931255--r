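test_that("AUC equals brute-force pair enumeration", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(compute_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  set.seed(1)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    sc <- round(runif(n), 2)  # rounded scores force ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(compute_auc(sc, lb), auc_bruteforce(sc, lb), tolerance = 1e-12)
  }
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "undefined AUC")
  # independent library cross-check
  skip_if_not_installed("pROC")
  set.seed(2)
  sc <- runif(80); lb <- rbinom(80, 1, 0.5)
  expect_equal(compute_auc(sc, lb),
               as.numeric(suppressMessages(pROC::auc(lb, sc, direction = "<"))),
               tolerance = 1e-12)
})

test_that("feature matrices carry the class arity and labels", {
  coh <- generate_cohort(10, 0.5, seed = 2)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 6, seed = 3)
  expect_equal(ncol(build_feature_matrix(pt, coh, "short")$x), 8)
  expect_equal(ncol(build_feature_matrix(pt, coh, "long")$x), 9)
  fm_all <- build_feature_matrix(pt, coh, "all_home")
  expect_equal(nrow(fm_all$x),
               nrow(build_feature_matrix(pt, coh, "short")$x) +
                 nrow(build_feature_matrix(pt, coh, "medium")$x) +
                 nrow(build_feature_matrix(pt, coh, "long")$x))
  expect_true(all(fm_all$label %in% c("faller", "non_faller")))
  expect_error(build_feature_matrix(pt, coh, "lab"), "empty feature matrix")
})

test_that("LOSO honours the fold contract and the PCA variance floor", {
  cfg <- load_config()
  coh <- generate_cohort(10, 0.5, seed = 4)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 6, classes = "short",
                                 seed = 5)
  fm <- build_feature_matrix(pt, coh, "short")
  out <- loso_feature_classifiers(fm, "LR", cfg, seed = 6, n_draws = 0)
  # fold count equals subject count; each subject scored exactly out-of-fold
  expect_equal(length(unique(out$scores$fold)), 10)
  expect_setequal(unique(out$scores$subject_id), coh$subject_id)
  for (s in coh$subject_id) {
    expect_equal(length(unique(out$scores$fold[out$scores$subject_id == s])), 1)
  }
  # retained components explain >= 95% of training variance in every fold
  ns <- asNamespace("msfallrisk")
  red <- ns$fit_reducer(fm$x[fm$subject_id != coh$subject_id[1], ], 0.95)
  expect_gte(red$explained, 0.95)
  # mutation test: the fitted transform ignores held-out rows entirely
  x2 <- fm$x
  x2[fm$subject_id == coh$subject_id[1], ] <- 999
  red2 <- ns$fit_reducer(x2[fm$subject_id != coh$subject_id[1], ], 0.95)
  expect_identical(red$rotation, red2$rotation)
})

test_that("a perfectly separating feature yields near-perfect AUC", {
  coh <- generate_cohort(12, 0.5, seed = 7)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 5, classes = "short",
                                 seed = 8)
  sep <- ifelse(coh$fall_label == "faller", 10, -10)
  pt$rms_ap_g <- sep[match(pt$subject_id, coh$subject_id)] + rnorm(nrow(pt), 0, 0.1)
  fm <- build_feature_matrix(pt, coh, "short")
  out <- loso_feature_classifiers(fm, "LR", load_config(), seed = 9, n_draws = 0)
  expect_gte(out$auc_per_input, 0.95)
})

test_that("stride-sequence inputs follow the sliding-window rule", {
  b <- segment_bout(n_strides = 8, seed = 10)
  n <- nrow(b$strides)
  expect_equal(length(build_stride_inputs(b, k = 1)), n)
  expect_equal(length(build_stride_inputs(b, k = n + 1)), 0)
  if (n >= 5) {
    expect_equal(length(build_stride_inputs(b, k = n - 1)), 2)  # strides 1..k, 2..k+1
  }
  ins <- build_stride_inputs(b, k = 2)
  expect_equal(nrow(ins[[1]]), 6)
  # time length spans the k strides
  expect_equal(ncol(ins[[1]]),
               round(b$strides$next_fc_s[2] * FS) - round(b$strides$fc_s[1] * FS))
  # ABC channel is constant when requested
  insa <- build_stride_inputs(b, k = 2, include_abc = TRUE, abc = 77)
  expect_equal(nrow(insa[[1]]), 7)
  expect_equal(unique(insa[[1]][7, ]), 77)
  expect_error(build_stride_inputs(b, k = 2, include_abc = TRUE), "abc")
  # disjoint-block alternative
  expect_lte(length(build_stride_inputs(b, k = 2, step = 2)),
             ceiling(n / 2))
})

test_that("published architecture specs carry the documented layers", {
  a2 <- arch_lstm2()
  expect_equal(vapply(a2$layers, `[[`, 1, "units"), c(290, 10))
  expect_equal(vapply(a2$layers, `[[`, 1, "dropout"), c(0.30, 0.40))
  expect_equal(vapply(a2$layers, `[[`, "", "type"), c("lstm", "bilstm"))
  expect_equal(a2$epochs, 55)
  a3 <- arch_lstm3()
  expect_equal(vapply(a3$layers, `[[`, 1, "units"), c(85, 85, 235))
  expect_equal(vapply(a3$layers, `[[`, 1, "dropout"), c(0.55, 0.55, 0.45))
  expect_equal(a3$epochs, 125)
})

test_that("modified LOSO keeps train/validation/test disjoint and aggregates medians", {
  # small separable cohort, reduced architecture
  effects <- c(ap_amplitude = 0.5, stride_time_mean = 1.25)
  coh <- generate_cohort(6, 0.5, effect_config = effects, seed = 11)
  inputs <- list(); sid <- character(0); lab <- character(0)
  for (i in seq_len(nrow(coh))) {
    b <- segment_bout(coh[i, ], n_strides = 6, seed = 50 + i,
                      subject_id = coh$subject_id[i])
    ins <- build_stride_inputs(b, k = 2)
    inputs <- c(inputs, ins)
    sid <- c(sid, rep(coh$subject_id[i], length(ins)))
    lab <- c(lab, rep(coh$fall_label[i], length(ins)))
  }
  arch <- lstm_spec(list(list(type = "lstm", units = 6, dropout = 0.1)),
                    epochs = 4, lr = 0.02)
  out <- loso_sequence_classification(inputs, sid, lab, arch, seed = 12)
  for (f in out$folds) {
    expect_length(intersect(f$train, c(f$test, f$validation)), 0)
    expect_false(f$test == f$validation)
  }
  expect_true(all(out$scores$score >= 0 & out$scores$score <= 1))
  # median aggregation definition
  med <- aggregate(score ~ subject_id, out$scores, median)
  s1 <- out$scores[out$scores$subject_id == med$subject_id[1], "score"]
  expect_equal(med$score[1], median(s1))
})
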