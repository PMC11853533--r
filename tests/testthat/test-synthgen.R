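test_that("generators are pure functions of config and seed", {
  cfg <- synth_config(seed = 5, n_subjects = 2, n_trials = 4)
  s <- pattern_schedule()
  e1 <- synth_eeg_trial(cfg, s, 2, window = c(-1, 6), seed = 9)
  e2 <- synth_eeg_trial(cfg, s, 2, window = c(-1, 6), seed = 9)
  expect_identical(e1$samples, e2$samples)
  p1 <- synth_pupil_trial(cfg, s, 3, seed = 9)
  p2 <- synth_pupil_trial(cfg, s, 3, seed = 9)
  expect_identical(p1$left, p2$left)
  d1 <- synth_dataset(cfg, modalities = "pupil")
  d2 <- synth_dataset(cfg, modalities = "pupil")
  expect_identical(d1$subjects, d2$subjects)
})

test_that("datasets balance the four targets within each subject", {
  cfg <- synth_config(seed = 3, n_subjects = 2, n_trials = 4)
  d <- synth_dataset(cfg, modalities = "pupil")
  for (s in d$subjects) {
    expect_setequal(vapply(s, `[[`, 0, "target_led"), 1:4)
  }
  cfg2 <- synth_config(seed = 3, n_subjects = 2, n_trials = 8)
  d2 <- synth_dataset(cfg2, modalities = "pupil")
  tgt <- unlist(lapply(d2$subjects, function(s) vapply(s, `[[`, 0, "target_led")))
  expect_equal(as.integer(table(tgt)), rep(4L, 4))
})

test_that("EEG samples before the first transition carry no stimulus signal", {
  s <- pattern_schedule()
  base <- synth_config(seed = 8, fvep_amplitude = 0, ssvep_amplitude = 0,
                       covariance_shift_scale = 0, sync_amplitude = 0)
  loud <- synth_config(seed = 8, fvep_amplitude = 10, ssvep_amplitude = 0,
                       covariance_shift_scale = 0, sync_amplitude = 0)
  e0 <- synth_eeg_trial(base, s, 1, window = c(-1, 6), seed = 4)
  e1 <- synth_eeg_trial(loud, s, 1, window = c(-1, 6), seed = 4)
  pre <- segment_times(e0) < 0
  expect_identical(e0$samples[, pre], e1$samples[, pre])
  expect_gt(max(abs(e0$samples[, !pre] - e1$samples[, !pre])), 0)
})

test_that("frequency-mode trials concentrate power at the target frequency", {
  cfg <- synth_config(seed = 12, eeg_channels = c("O1", "Oz", "O2"))
  f <- frequency_schedule()
  e <- synth_eeg_trial(cfg, f, 4, window = c(0, 5), seed = 2)
  oz <- e$samples["Oz", ]
  sp <- stats::spec.pgram(oz, plot = FALSE, taper = 0)
  freq_hz <- sp$freq * 500
  p_at <- function(f0) max(sp$spec[abs(freq_hz - f0) < 0.3])
  expect_gt(p_at(10), p_at(7.5))
})

test_that("flash transients are locked to the gazed LED's transitions", {
  # LED2's onsets share no transition time with LED1's, so the cross-locked
  # average sees no coherent component (LED pairs with coincident
  # transitions, e.g. LED1-off/LED2-on at 0.5 s, would)
  cfg <- synth_config(seed = 13, sync_amplitude = 0, fvep_amplitude = 10,
                      noise_sd = 2)
  s <- pattern_schedule()
  e <- synth_eeg_trial(cfg, s, 2, window = c(-1, 6), seed = 6)
  filt <- bandpass(e, 2, 30, "butterworth", 3)
  own <- peak_to_valley(averaged_fvep(filt, s, 2, "onset"))
  other <- peak_to_valley(averaged_fvep(filt, s, 1, "onset"))
  expect_gt(own, 3 * other)
})

test_that("pupil traces constrict with the gazed LED and diverge after 2.5 s", {
  s <- pattern_schedule()
  cfg <- synth_config(seed = 21)
  # zero gain: flat up to hippus + noise
  flat_cfg <- synth_config(seed = 21, plr_constriction_gain = 0, blink_rate = 0)
  flat <- synth_pupil_trial(flat_cfg, s, 1, seed = 3)
  expect_lt(diff(range(flat$left)), 0.3)
  # gazing LED1 produces repeated constriction minima in 0-4.5 s
  p1 <- synth_pupil_trial(synth_config(seed = 21, blink_rate = 0), s, 1, seed = 3)
  w <- crop_pupil(p1, 0, 4.5)
  d <- w$left
  minima <- which(diff(sign(diff(d))) > 0) + 1
  deep <- minima[d[minima] < mean(d[1:10]) - 0.2]
  expect_gte(length(unique(round(deep / 10))), 2)
  # LED2 goes dark at 2.5 s, LED3 keeps flickering: traces diverge late
  p2 <- synth_pupil_trial(synth_config(seed = 21, blink_rate = 0), s, 2, seed = 3)
  p3 <- synth_pupil_trial(synth_config(seed = 21, blink_rate = 0), s, 3, seed = 3)
  late <- function(p) mean(crop_pupil(p, 3, 4.5)$left)
  expect_gt(late(p2), late(p3) + 0.1)
})

test_that("EMG bursts appear only while chewing, at the configured rate", {
  cfg <- synth_config(seed = 30)
  quiet <- synth_emg(cfg, chewing = FALSE, duration = 6)
  expect_null(emg_chew_trigger(quiet))
  chew <- synth_emg(cfg, chewing = TRUE, duration = 10, chew_from = 2)
  tg <- emg_chew_trigger(chew)
  expect_false(is.null(tg))
  expect_true(tg$time >= 2 && tg$time <= 2.5)
  # burst count via envelope threshold: 1.5 Hz over ~9.7 s of chewing
  filt <- bandpass(chew, 20, 150, "butterworth", 4)
  env <- stats::filter(abs(filt$samples[1, ]), rep(1 / 50, 50), sides = 2)
  thr <- 3 * stats::sd(env[1:900], na.rm = TRUE) + mean(env[1:900], na.rm = TRUE)
  runs <- rle(as.vector(!is.na(env) & env > thr))
  n_bursts <- sum(runs$values & runs$lengths > 25)
  expect_gte(n_bursts, 9)
  expect_lte(n_bursts, 15)
})

test_that("blink dropouts appear at the configured rate as low confidence", {
  s <- pattern_schedule()
  no_blink <- synth_pupil_trial(synth_config(seed = 40, blink_rate = 0), s, 1, seed = 2)
  expect_true(all(no_blink$conf_left > 0.6))
  many <- lapply(1:8, function(i) {
    synth_pupil_trial(synth_config(seed = 40, blink_rate = 20), s, 1, seed = 100 + i)
  })
  frac_low <- mean(vapply(many, function(p) mean(p$conf_left < 0.6), 0))
  expect_gt(frac_low, 0.005)
})
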