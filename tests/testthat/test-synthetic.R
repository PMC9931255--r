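test_that("cohort generation respects counts, determinism and effects", {
  coh <- generate_cohort(38, 21 / 38, seed = 1)
  expect_equal(sum(coh$fall_label == "faller"), 21)
  expect_equal(sum(coh$fall_label == "non_faller"), 17)
  expect_identical(coh, generate_cohort(38, 21 / 38, seed = 1))

  # empty faller set: effects never applied
  coh0 <- generate_cohort(10, 0, effect_config = c(ap_amplitude = 0.01), seed = 7)
  expect_true(all(coh0$fall_label == "non_faller"))
  expect_true(all(coh0$ap_amplitude > 0.04))

  # empirical group-mean ratio tracks the configured multiplier
  cohe <- generate_cohort(200, 0.5, effect_config = c(ap_amplitude = 0.85), seed = 3)
  ratio <- mean(cohe$ap_amplitude[cohe$fall_label == "faller"]) /
    mean(cohe$ap_amplitude[cohe$fall_label == "non_faller"])
  expect_lt(abs(ratio - 0.85), 0.04)

  expect_error(generate_cohort(10, 0.5, effect_config = c(bogus = 2)),
               "unknown parameter")
})

test_that("cohort profiles satisfy their invariants", {
  coh <- generate_cohort(60, 0.4, seed = 11)
  expect_true(all(coh$stride_time_mean >= 0.5 & coh$stride_time_mean <= 3))
  expect_true(all(coh$stride_time_cv >= 0))
  expect_true(all(coh$duty_factor_mean > 0.5 & coh$duty_factor_mean < 0.8))
  expect_true(all(coh$ap_amplitude > 0))
  expect_true(all(coh$abc <= 100 & coh$abc >= 0, na.rm = TRUE))
  expect_true(all(coh$edss <= 10 & coh$edss >= 0))
})

test_that("walking segments honour stride-time statistics and duty factor", {
  # zero-variance case: identical strides, exact duty factor
  p0 <- ref_profile(stride_time_cv = 0, duty_factor_mean = 0.62)
  seg0 <- synth_walking_segment(p0, 10, FS, seed = 2)
  expect_equal(length(unique(round(seg0$stride_s, 9))), 1)
  # all duty factors identical; grid snapping perturbs the value by less than
  # one sample per stride
  expect_equal(length(unique(round(seg0$duty, 9))), 1)
  expect_true(all(abs(seg0$duty - 0.62) < 1 / (FS * min(seg0$stride_s))))

  # stride-time mean recovered at n = 50
  seg <- synth_walking_segment(ref_profile(stride_time_mean = 1.16), 50, FS, 5)
  expect_lt(abs(mean(seg$stride_s) - 1.16) / 1.16, 0.02)

  # mean/CV reproduced within 5% at n = 200
  p <- ref_profile(stride_time_mean = 1.3, stride_time_cv = 0.08)
  segl <- synth_walking_segment(p, 200, FS, 9)
  expect_lt(abs(mean(segl$stride_s) - 1.3) / 1.3, 0.05)
  cv_hat <- sd(segl$stride_s) / mean(segl$stride_s)
  expect_lt(abs(cv_hat - 0.08) / 0.08, 0.2)

  expect_error(synth_walking_segment(ref_profile(), 0), "n_strides")
})

test_that("chest AP RMS scales exactly linearly with ap_amplitude", {
  p1 <- ref_profile(ap_amplitude = 0.14)
  p2 <- ref_profile(ap_amplitude = 0.28)
  s1 <- synth_walking_segment(p1, 12, FS, seed = 4)
  s2 <- synth_walking_segment(p2, 12, FS, seed = 4)
  r1 <- sqrt(mean(s1$chest["ap", ]^2))
  r2 <- sqrt(mean(s2$chest["ap", ]^2))
  expect_equal(r2 / r1, 2, tolerance = 1e-12)
})

test_that("event ordering invariant holds in generated segments", {
  for (seed in 1:5) {
    seg <- synth_walking_segment(ref_profile(stride_time_cv = 0.1), 30, FS, seed)
    n <- length(seg$stride_s)
    fc <- seg$events$fc_s; fo <- seg$events$fo_s
    expect_true(all(fo[seq_len(n)] > fc[seq_len(n)]))
    expect_true(all(fo[seq_len(n)] < fc[seq_len(n) + 1]))
  }
})

test_that("subject recordings obey the bout mixture and window quantum", {
  p <- generate_cohort(2, 0, seed = 1)[1, ]
  rec <- generate_subject_recording(p, 1.5, seed = 6)
  tr <- rec$truth
  expect_true(all((tr$bouts$end_s - tr$bouts$start_s) %% 4 == 0))
  # disjoint sorted bouts
  expect_true(all(diff(tr$bouts$start_s) > 0))
  expect_true(all(tr$bouts$start_s[-1] >= tr$bouts$end_s[-nrow(tr$bouts)]))
  # events inside their bout
  for (i in seq_len(nrow(tr$bouts))) {
    ev <- tr$events[[i]]
    expect_true(all(ev$fc_s >= tr$bouts$start_s[i] & ev$fc_s < tr$bouts$end_s[i]))
  }
  # label vector consistent with bouts
  expect_equal(sum(tr$window_labels) * 4, sum(tr$bouts$end_s - tr$bouts$start_s))

  # degenerate mixture: all short
  recs <- generate_subject_recording(p, 0.3, bout_mix = c(short = 1, medium = 0, long = 0),
                                     seed = 8)
  expect_true(all(recs$truth$bouts$end_s - recs$truth$bouts$start_s <= 8))

  # determinism
  ra <- generate_subject_recording(p, 0.2, seed = 9)
  rb <- generate_subject_recording(p, 0.2, seed = 9)
  expect_identical(ra$chest$data, rb$chest$data)
  expect_identical(ra$truth, rb$truth)

  expect_error(generate_subject_recording(p, 1, bout_mix = c(short = 0.7, medium = 0.2, long = 0.2)),
               "sum to 1")
})

test_that("bout class proportions track the requested mixture", {
  p <- generate_cohort(2, 0, seed = 1)[1, ]
  mix <- c(short = 0.61, medium = 0.32, long = 0.07)
  cls <- character(0)
  for (s in 1:4) {
    rec <- generate_subject_recording(p, 1, mix, seed = 20 + s)
    cls <- c(cls, rec$truth$bouts$class)
  }
  emp <- table(factor(cls, levels = names(mix))) / length(cls)
  expect_true(all(abs(emp - mix) < 0.05))
})

test_that("simulated bout parameter tables track profile ground truth", {
  coh <- generate_cohort(12, 0.5, seed = 3)
  pt <- simulate_bout_parameters(coh, bouts_per_subject = 40, classes = "short",
                                 seed = 4)
  agg <- aggregate(cbind(rms_ap_g, duty_factor_mean, stride_time_mean_s) ~ subject_id,
                   pt, mean)
  m <- merge(agg, coh, by = "subject_id")
  expect_gt(cor(m$rms_ap_g, m$ap_amplitude), 0.95)
  expect_gt(cor(m$stride_time_mean_s, m$stride_time_mean), 0.95)
  fit <- coef(lm(m$rms_ap_g ~ m$ap_amplitude))
  expect_lt(abs(fit[2] - 1), 0.1)
})
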