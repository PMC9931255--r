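test_that("duration classes follow the 8/12-28/32 bounds", {
  expect_equal(categorize_bout_duration(c(4, 8)), c("short", "short"))
  expect_equal(categorize_bout_duration(c(12, 20, 28)), rep("medium", 3))
  expect_equal(categorize_bout_duration(c(32, 60, 120)), rep("long", 3))
  expect_error(categorize_bout_duration(10), "quantization")
  expect_error(categorize_bout_duration(7), "quantization")
})

test_that("subject summaries produce the seven ordered statistics", {
  pt <- data.frame(subject_id = "A", duration_class = "short",
                   rms_ap_g = 5, stride_time_mean_s = 1.1,
                   stance_time_mean_s = 0.7, swing_time_mean_s = 0.4,
                   stride_time_cv = 0.06, duty_factor_mean = 0.62,
                   duty_factor_cv = 0.04, freqd_ml_hz = 0.6)
  s1 <- summarize_subject(pt, "A", "short")
  # single bout: all location stats equal the value, sd = 0
  for (st in c("mean", "median", "max", "min", "p5", "p95")) {
    expect_equal(s1[[paste0(st, "_rms_ap_g")]], 5)
  }
  expect_equal(s1$sd_rms_ap_g, 0)

  # closed-form percentiles under linear interpolation
  pt2 <- do.call(rbind, replicate(100, pt, simplify = FALSE))
  pt2$rms_ap_g <- 1:100
  s2 <- summarize_subject(pt2, "A", "short")
  expect_equal(s2$p5_rms_ap_g, 5.95)
  expect_equal(s2$p95_rms_ap_g, 95.05)

  # ordering invariant on random inputs
  set.seed(1)
  for (rep in 1:5) {
    pt3 <- pt2; pt3$rms_ap_g <- rnorm(100)
    s3 <- summarize_subject(pt3, "A", "short")
    v <- unlist(s3[paste0(c("min", "p5", "median", "p95", "max"), "_rms_ap_g")])
    expect_true(all(diff(v) >= 0))
    expect_gte(s3$sd_rms_ap_g, 0)
  }

  expect_null(summarize_subject(pt, "A", "long"))
})

test_that("Wilcoxon rank-sum matches exact enumeration and handles edge cases", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_false(r$significant)

  # identical samples: no crash, not significant
  same <- wilcoxon_rank_sum(rep(2, 5), rep(2, 4))
  expect_gte(same$p_value, 0.99)

  a <- c(3.2, 1.1, 4.8, 2.2)
  self <- wilcoxon_rank_sum(a, a)
  expect_gte(self$p_value, 0.99)

  # exhaustive agreement with full enumeration for all n_a, n_b <= 6
  set.seed(2)
  for (na in 2:6) for (nb in 2:6) {
    x <- rnorm(na); y <- rnorm(nb) + 0.8
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-9,
                 label = sprintf("exact p (n=%d,%d)", na, nb))
  }

  # power against a clear shift at large n
  set.seed(3)
  hits <- replicate(50, wilcoxon_rank_sum(rnorm(60), rnorm(60) + 1)$significant)
  expect_gte(mean(hits), 0.99)
})

test_that("comparison suite finds configured effects in the expected direction", {
  cfg <- load_config()
  coh <- generate_cohort(38, 21 / 38, seed = 10)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 20, seed = 11)
  suite <- suppressWarnings(comparison_suite(pt, coh, cfg))
  fr <- suite$fall_risk
  expect_true(all(fr$p_value >= 0 & fr$p_value <= 1))
  expect_true(all(fr$significant == (fr$p_value < cfg$alpha)))
  # manipulated parameters flagged, faller median below non-faller median
  manip <- fr[fr$significant & grepl("rms_ap_g$|duty_factor_mean$", fr$feature), ]
  expect_gt(nrow(manip), 0)
  expect_true(all(manip$median_a < manip$median_b))

  # single-duration dataset: only within-duration comparisons emitted
  pts <- pt[pt$duration_class == "short", ]
  st <- suppressWarnings(comparison_suite(pts, coh, cfg))
  expect_true(all(grepl("short", st$fall_risk$comparison_id)))
  expect_null(st$duration)
})

test_that("duration and context suites mirror the table layouts", {
  cfg <- load_config()
  coh <- generate_cohort(10, 0.5, seed = 12)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 10, seed = 13)
  lab <- simulate_bout_parameters(coh, bouts_per_subject = 2, classes = "long",
                                  seed = 14)
  lab$context <- "lab"; lab$duration_class <- "lab"
  suite <- comparison_suite(rbind(pt, lab), coh, cfg)
  expect_setequal(unique(suite$duration$comparison_id),
                  c("short_vs_medium", "short_vs_long", "medium_vs_long"))
  expect_setequal(unique(suite$context$comparison_id),
                  c("lab_vs_short", "lab_vs_medium", "lab_vs_long", "lab_vs_all_home"))
  # lab-vs-long adds the entropy ratio
  expect_true("entropy_ratio" %in%
                suite$context$feature[suite$context$comparison_id == "lab_vs_long"])
  expect_false("entropy_ratio" %in%
                 suite$context$feature[suite$context$comparison_id == "lab_vs_short"])
})

test_that("kNN survey imputation matches brute-force neighbour search", {
  coh <- generate_cohort(12, 0.5, seed = 20)
  expect_identical(impute_surveys_knn(coh), coh)  # no missing: unchanged

  # zero-distance clones: imputed value equals the clone value
  clone <- coh[rep(1, 6), ]
  clone$subject_id <- sprintf("C%02d", 1:6)
  clone$nsi[6] <- NA
  imp <- impute_surveys_knn(clone)
  expect_equal(imp$nsi[6], coh$nsi[1])

  # oracle equivalence on a random table
  set.seed(21)
  coh2 <- generate_cohort(15, 0.5, seed = 22)
  coh2$msws[c(3, 9)] <- NA
  imp2 <- impute_surveys_knn(coh2, k = 3)
  fields <- c("abc", "edss", "mfis", "msws", "nsi")
  x <- as.matrix(coh2[, fields])
  complete <- complete.cases(x)
  mu <- colMeans(x[complete, ]); sdv <- apply(x[complete, ], 2, sd)
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  for (i in c(3, 9)) {
    use <- setdiff(seq_along(fields), which(is.na(x[i, ])))
    d <- apply(z[complete, use], 1, function(r) sqrt(sum((r - z[i, use])^2)))
    expected <- mean(x[which(complete)[order(d)[1:3]], "msws"])
    expect_equal(imp2$msws[i], expected)
  }

  coh3 <- coh[1:4, ]; coh3$abc[1:2] <- NA; coh3$nsi[3:4] <- NA
  expect_error(impute_surveys_knn(coh3, k = 3), "fewer than k")
})
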