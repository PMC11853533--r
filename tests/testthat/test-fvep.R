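test_that("averaged responses use every schedule transition of the LED", {
  s <- pattern_schedule()
  cfg <- synth_config(seed = 70, sync_amplitude = 0)
  e <- synth_eeg_trial(cfg, s, 1, window = c(-1, 6), seed = 3)
  filt <- bandpass(e, 2, 30, "butterworth", 3)
  avg <- averaged_fvep(filt, s, 1, "onset")
  expect_equal(attr(avg, "n_epochs"), 5L)       # LED1: 5 on-transitions
  expect_equal(ncol(avg$samples), 225L)
  expect_equal(avg$t0, -0.1)
  # waveform peak lands within 200 ms of the transition for a gazed trial
  w <- colMeans(avg$samples)
  t_pk <- (which.max(abs(w[51:225])) - 1) / 500
  expect_lt(t_pk, 0.2)
  expect_error(averaged_fvep(filt, s, 2, "onset", stim_onset = 90), "epochs")
})

test_that("peak-to-valley is the max minus min and offset-invariant", {
  flat <- mc_segment(matrix(1, 2, 225), 500, t0 = -0.1)
  expect_equal(peak_to_valley(flat), 0)
  v <- c(rep(0, 50), 0, 2, -1, 0.5, rep(0, 171))
  seg <- mc_segment(rbind(a = v, b = v), 500, t0 = -0.1)
  expect_equal(peak_to_valley(seg), 3)
  expect_equal(peak_to_valley(mc_segment(rbind(a = v + 7, b = v + 7), 500,
                                         t0 = -0.1)), 3)
  expect_error(peak_to_valley(seg, c(400, 500)), "window")
})

test_that("noise-free averaged amplitude recovers the injected kernel", {
  s <- pattern_schedule()
  amp <- 6
  cfg <- synth_config(seed = 71, fvep_amplitude = amp, noise_sd = 1e-4,
                      sync_amplitude = 0)
  e <- synth_eeg_trial(cfg, s, 1, window = c(-1, 6), seed = 4)
  p2v <- peak_to_valley(averaged_fvep(e, s, 1, "onset"))
  kern <- fvep_kernel(seq(0, 0.35, by = 1 / 500), cfg$fvep_latency)
  expect_equal(p2v, amp * (max(kern) - min(kern)), tolerance = 0.01)
})

test_that("trial features are label-blind with one pair per LED", {
  s <- pattern_schedule()
  cfg <- synth_config(seed = 72)
  e <- synth_eeg_trial(cfg, s, 3, window = c(-1, 6), seed = 5)
  filt <- bandpass(e, 2, 30, "butterworth", 3)
  fe <- extract_trial_features(filt, s)
  expect_equal(dim(fe), c(4L, 2L))
  expect_true(all(fe >= 0))
  # the gazed LED's own row dominates
  expect_equal(unname(which.max(rowSums(unclass(fe)))), 3L)
  # features never look at the label: recomputation is identical
  expect_identical(unclass(extract_trial_features(filt, s)), unclass(fe))
})

test_that("target amplitude grows with the generator amplitude, non-target does not", {
  s <- pattern_schedule()
  levels <- c(2, 5, 10)
  own <- other <- numeric(3)
  for (j in 1:3) {
    vals_own <- vals_oth <- c()
    for (i in 1:4) {
      cfg <- synth_config(seed = 73, fvep_amplitude = levels[j],
                          sync_amplitude = 0)
      e <- synth_eeg_trial(cfg, s, 1, window = c(-1, 6), seed = 900 + i)
      fe <- extract_trial_features(bandpass(e, 2, 30, "butterworth", 3), s)
      vals_own <- c(vals_own, fe[1, 1])
      vals_oth <- c(vals_oth, fe[3, 1])
    }
    own[j] <- mean(vals_own)
    other[j] <- mean(vals_oth)
  }
  expect_true(all(diff(own) > 0))
  expect_lt(diff(range(other)), 0.5 * diff(range(own)))
})

test_that("per-LED models are trained by seeded grid search and combined by margin", {
  # well-separated synthetic feature matrices
  set.seed(74)
  mk_feat <- function(target) {
    m <- matrix(abs(rnorm(8, 3, 0.5)), 4, 2)
    m[target, ] <- m[target, ] + 10
    structure(m, class = c("fvep_features", "matrix", "array"))
  }
  labs <- rep(1:4, each = 10)
  feats <- lapply(labs, mk_feat)
  models <- train_led_models(feats, labs, seed = 4)
  expect_s3_class(models, "fvep_models")
  for (k in 1:4) {
    sel <- models[[k]]$selected
    expect_true(sel$cost %in% models[[k]]$grid$cost)
    expect_gte(models[[k]]$cv_score, 0.9)
  }
  # determinism of the selected grid point
  models2 <- train_led_models(feats, labs, seed = 4)
  for (k in 1:4) expect_equal(models[[k]]$selected, models2[[k]]$selected)
  # training accuracy on separable features
  pred <- vapply(feats, function(f) combine_decisions(models, f)$predicted_led, 0L)
  expect_gte(mean(pred == labs), 0.95)
  expect_error(train_led_models(feats[labs == 1], labs[labs == 1]),
               "single class")
  expect_error(combine_decisions(structure(list(models[[1]]),
                                           class = "fvep_models"),
                                 feats[[1]]), "four")
})

test_that("shuffled labels give chance-level cross-validation scores", {
  set.seed(75)
  feats <- lapply(1:40, function(i) {
    structure(matrix(abs(rnorm(8, 3, 1)), 4, 2),
              class = c("fvep_features", "matrix", "array"))
  })
  labs <- rep(1:4, each = 10)
  models <- train_led_models(feats, labs, seed = 6)
  cv <- mean(vapply(models, `[[`, 0, "cv_score"))
  # binary problems with 25/75 class balance: chance is ~0.75
  expect_lt(abs(cv - 0.75), 0.12)
})
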