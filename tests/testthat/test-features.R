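test_that("temporal parameters reproduce hand-computed values", {
  s <- data.frame(stride_s = rep(1.16, 5), stance_s = rep(0.71, 5),
                  swing_s = rep(0.45, 5))
  s$duty_factor <- s$stance_s / s$stride_s
  tp <- temporal_parameters(s)
  expect_equal(tp$stride_time_mean_s, 1.16)
  expect_equal(tp$stance_time_mean_s, 0.71)
  expect_equal(tp$swing_time_mean_s, 0.45)
  expect_equal(tp$stride_time_cv, 0)
  expect_equal(tp$duty_factor_mean, 0.71 / 1.16, tolerance = 1e-12)

  s2 <- data.frame(stride_s = c(1.0, 1.2), stance_s = c(0.6, 0.8),
                   swing_s = c(0.4, 0.4))
  s2$duty_factor <- s2$stance_s / s2$stride_s
  tp2 <- temporal_parameters(s2)
  expect_equal(tp2$stride_time_mean_s, 1.1)
  expect_equal(tp2$stride_time_cv, sd(c(1, 1.2)) / 1.1, tolerance = 1e-12)
  expect_equal(round(tp2$stride_time_cv, 4), 0.1286)

  # scale invariance of CV
  s3 <- s2; s3[c("stride_s", "stance_s", "swing_s")] <- s3[c("stride_s", "stance_s", "swing_s")] * 2
  tp3 <- temporal_parameters(s3)
  expect_equal(tp3$stride_time_mean_s, 2 * tp2$stride_time_mean_s)
  expect_equal(tp3$stride_time_cv, tp2$stride_time_cv)

  expect_error(temporal_parameters(s2[1, ]), "insufficient strides")
})

test_that("RMS AP matches closed forms and the brute-force formula", {
  expect_equal(rms_ap(rep(0, 100)), 0)
  t <- (0:9999) / 100
  A <- 0.3
  expect_equal(rms_ap(A * sin(2 * pi * 2 * t)), A / sqrt(2), tolerance = 1e-3)
  set.seed(2)
  x <- rnorm(500)
  xm <- x - mean(x)
  expect_equal(rms_ap(x), sqrt(sum(xm^2) / 500), tolerance = 1e-12)
  # offset invariance (mean removal)
  expect_equal(rms_ap(x + 5), rms_ap(x), tolerance = 1e-12)
})

test_that("frequency dispersion matches point-spectrum and white-noise forms", {
  fs <- FS
  t <- (0:(60 * fs - 1)) / fs
  tone <- sin(2 * pi * 1.3 * t)
  expect_lt(freq_dispersion_ml(tone, fs), 0.15)  # bounded by resolution
  # white noise: uniform PSD over (0, fs/2] has SD B/sqrt(12)
  set.seed(3)
  disp <- replicate(4, freq_dispersion_ml(rnorm(round(120 * fs)), fs))
  expect_lt(abs(mean(disp) - (fs / 2) / sqrt(12)), 0.25)
  # amplitude invariance
  expect_equal(freq_dispersion_ml(3 * tone, fs), freq_dispersion_ml(tone, fs),
               tolerance = 1e-9)
  expect_error(freq_dispersion_ml(rep(0, 1000), fs), "undefined dispersion")
})

test_that("sample entropy matches the independent oracle and orders regularity", {
  skip_if_not_installed("pracma")
  set.seed(4)
  x <- sin(2 * pi * (1:800) / 37) + rnorm(800, 0, 0.3)
  expect_equal(sample_entropy(x),
               pracma::sample_entropy(x, edim = 2, r = 0.2 * sd(x)),
               tolerance = 1e-12)
  # periodic is more regular than noise
  per <- sin(2 * pi * (1:800) / 37)
  wn <- rnorm(800)
  expect_lt(sample_entropy(per), sample_entropy(wn))
})

test_that("entropy ratio is reciprocal and orders noise against gait", {
  seg <- synth_walking_segment(ref_profile(), 35, FS, seed = 5)
  n <- 1200
  thigh <- seg$thigh[, 1:n]; chest <- seg$chest[, 1:n]
  expect_equal(entropy_ratio(chest, chest), 1)
  r_ab <- entropy_ratio(thigh, chest)
  r_ba <- entropy_ratio(chest, thigh)
  expect_equal(r_ab * r_ba, 1, tolerance = 1e-9)
  # white-noise "thigh" vs near-periodic chest: ratio > 1
  set.seed(6)
  noise <- matrix(rnorm(3 * n, 0, 0.2), 3); rownames(noise) <- c("v", "ml", "ap")
  expect_gt(entropy_ratio(noise, chest), 1)
})

test_that("Lyapunov estimate is near zero for periodic signals and grows with noise", {
  fs <- FS
  t <- (0:(70 * fs - 1)) / fs
  per <- sin(2 * pi * 0.9 * t) + 0.4 * sin(2 * pi * 1.8 * t + 0.5)
  ly0 <- max_lyapunov(per, fs, 0.9)
  expect_lte(ly0, 0.05)
  set.seed(7)
  lys <- vapply(c(0.05, 0.15, 0.4), function(s)
    max_lyapunov(per + rnorm(length(per), 0, s), fs, 0.9), 1)
  expect_true(all(diff(c(ly0, lys)) > -1e-9))
  # time reversal: finite estimate, no crash
  expect_true(is.finite(max_lyapunov(rev(per + rnorm(length(per), 0, 0.1)), fs, 0.9)))
})

test_that("feature arity is 8/9/11 by bout class", {
  cfg <- load_config()
  count_feats <- function(p) {
    cols <- c("stride_time_mean_s", "stance_time_mean_s", "swing_time_mean_s",
              "stride_time_cv", "duty_factor_mean", "duty_factor_cv",
              "rms_ap_g", "freqd_ml_hz", "entropy_ratio", "ly_ap_per_s",
              "ly_ml_per_s")
    sum(!is.na(unlist(p[cols])))
  }
  b8 <- segment_bout(n_strides = 8, seed = 31)   # trimmed to 8 s
  b8$chest <- b8$chest[, 1:250]; b8$thigh <- b8$thigh[, 1:250]
  b8$duration_s <- 8; b8$end_s <- 8
  b8$strides <- detect_gait_events(b8$thigh, FS)
  p8 <- extract_bout_parameters(b8, "home", cfg)
  expect_equal(count_feats(p8), 8)
  expect_equal(p8$duration_class, "short")

  b40 <- segment_bout(n_strides = 38, seed = 32)
  b40$chest <- b40$chest[, 1:(40 * 125 / 4)]    # 40 s
  b40$thigh <- b40$thigh[, 1:(40 * 125 / 4)]
  b40$duration_s <- 40; b40$end_s <- 40
  b40$strides <- detect_gait_events(b40$thigh, FS)
  p40 <- extract_bout_parameters(b40, "home", cfg)
  expect_equal(count_feats(p40), 9)
  expect_equal(p40$duration_class, "long")

  b64 <- segment_bout(n_strides = 58, seed = 33)
  p64 <- extract_bout_parameters(b64, "lab", cfg)
  expect_equal(count_feats(p64), 11)
  expect_equal(p64$duration_class, "lab")
})

test_that("bout-level estimates regress on generator truth with unit slope", {
  set.seed(8)
  truth <- list(); est <- list()
  for (i in 1:12) {
    p <- ref_profile(stride_time_mean = runif(1, 0.9, 1.6),
                     stride_time_cv = runif(1, 0.03, 0.12),
                     duty_factor_mean = runif(1, 0.56, 0.68),
                     ap_amplitude = runif(1, 0.08, 0.25))
    b <- segment_bout(p, n_strides = 25, seed = 400 + i)
    tp <- temporal_parameters(b$strides)
    truth[[i]] <- data.frame(st = mean(b$truth$stride_s),
                             duty = mean(b$truth$duty),
                             rms = p$ap_amplitude)
    est[[i]] <- data.frame(st = tp$stride_time_mean_s,
                           duty = tp$duty_factor_mean,
                           rms = rms_ap(b$chest["ap", ]))
  }
  tr <- do.call(rbind, truth); es <- do.call(rbind, est)
  for (v in c("st", "duty", "rms")) {
    fit <- lm(es[[v]] ~ tr[[v]])
    expect_lt(abs(coef(fit)[2] - 1), 0.1)
    expect_gt(summary(fit)$r.squared, 0.9)
  }
})
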