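#' Synthetic-data configuration
#'
#' Conditions of the emulated study: five subjects, 60 cued trials per
#' subject, 500 Hz eight-channel dry EEG, 30 Hz binocular pupillometry.
#' Amplitudes are in microvolts (EEG/EMG) and millimetres (pupil); the seed
#' fully determines every generated sample.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject (LED targets balanced).
#' @param eeg_rate,pupil_rate sampling rates, Hz.
#' @param eeg_channels channel label vector.
#' @param fvep_amplitude flash-locked transient amplitude, uV.
#' @param fvep_latency transient peak latency bound, ms (< 200).
#' @param ssvep_amplitude steady-state oscillation amplitude, uV
#'   (frequency mode).
#' @param noise_sd pink-background standard deviation per channel, uV.
#' @param sync_amplitude amplitude of the synchronized narrowband network
#'   source, uV; during rest it appears in short bursts, during the task it
#'   is sustained (the induced-gamma-like state the covariance analysis
#'   detects).
#' @param sync_freq frequency of the network source, Hz; the default is a
#'   low-gamma frequency inside the wide covariance-analysis band but
#'   outside the 2-30 Hz transient band and off the stimulation bank and
#'   its harmonics.
#' @param rest_burst_rate rate of rest-state synchronized bursts, 1/s
#'   (quasi-regular, jittered). Bursts are suppressed from 0.6 s before
#'   stimulus engagement to 0.5 s after stimulus end, emulating
#'   attention-related desynchronization around task onset.
#' @param covariance_shift_scale multiplier on the sustained task-state
#'   source; 0 removes the task-onset covariance change.
#' @param sync_task_delay delay between stimulus onset and the locked-in
#'   synchronized task state, s (the neural transition the covariance
#'   analysis detects).
#' @param plr_latency pupil response latency, ms.
#' @param plr_constriction_gain light-driven constriction depth, mm.
#' @param baseline_mm resting pupil diameter, mm.
#' @param blink_rate blink dropouts per minute.
#' @param chew_rate chewing burst rate, Hz.
#' @param emg_noise_sd EMG baseline standard deviation, uV.
#' @param onset_jitter_sd SD of the true stimulus onset around the cue, s
#'   (0 = perfectly cued, as in the offline experiments).
#' @param seed integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 5, n_trials = 60,
                         eeg_rate = 500, pupil_rate = 30,
                         eeg_channels = c("Fz", "Pz", "P4", "P3",
                                          "O1", "O2", "C3", "C4"),
                         fvep_amplitude = 5, fvep_latency = 110,
                         ssvep_amplitude = 2, noise_sd = 3,
                         sync_amplitude = 8, sync_freq = 38,
                         rest_burst_rate = 1.5,
                         covariance_shift_scale = 2,
                         sync_task_delay = 0.3,
                         plr_latency = 250, plr_constriction_gain = 0.8,
                         baseline_mm = 4, blink_rate = 2,
                         chew_rate = 1.5, emg_noise_sd = 5,
                         onset_jitter_sd = 0, seed = 1L) {
  cfg <- as.list(environment())
  if (eeg_rate <= 0 || pupil_rate <= 0) stop("rates must be positive")
  if (length(eeg_channels) < 1L) stop("eeg_channels must be non-empty")
  if (fvep_latency >= 200) stop("fvep_latency must be < 200 ms")
  if (covariance_shift_scale < 0) stop("covariance_shift_scale must be >= 0")
  structure(cfg, class = "synth_config")
}

# Small-integer seed derivation so every trial draws an independent but
# reproducible stream; kept below 2^31 - 1.
derive_seed <- function(seed, a, b = 0) {
  as.integer(((seed %% 100000) * 7919 + a * 104729 + b * 1299721) %% 2147483647)
}

# 1/f-amplitude noise, unit variance, via random-phase spectrum shaping.
pink_noise <- function(n) {
  nf <- n %/% 2
  amp <- 1 / sqrt(seq_len(nf))
  ph <- stats::runif(nf, 0, 2 * pi)
  half <- complex(modulus = amp, argument = ph)
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- half
  if (n %% 2 == 0) {
    spec[nf + 1] <- complex(modulus = amp[nf], argument = 0)
    if (nf > 1) spec[n:(nf + 2)] <- Conj(half[1:(nf - 1)])
  } else {
    spec[n:(nf + 2)] <- Conj(half[1:(nf - 1)])
    spec[nf + 2] <- Conj(half[nf])
  }
  x <- Re(stats::fft(spec, inverse = TRUE))
  as.numeric(scale(x))
}

#' Biphasic flash-evoked kernel
#'
#' Difference of two gamma-shaped bumps: positive lobe peaking at
#' 0.6 x latency, negative lobe at 1.3 x latency, maximum absolute value 1.
#' This is the transient the generator injects at every luminance
#' transition of the gazed LED.
#'
#' @param t_s time after the transition, seconds (vector).
#' @param latency_ms latency bound, ms.
#' @return numeric vector of kernel values.
#' @export
fvep_kernel <- function(t_s, latency_ms = 110) {
  tl <- latency_ms / 1000
  bump <- function(t, tp, q) ifelse(t > 0, (t / tp)^q * exp(q * (1 - t / tp)), 0)
  k <- bump(t_s, 0.6 * tl, 4) - 0.6 * bump(t_s, 1.3 * tl, 4)
  k / max(abs(fvep_kernel_raw(latency_ms)))
}

fvep_kernel_raw <- function(latency_ms) {
  tl <- latency_ms / 1000
  tt <- seq(0, 0.35, by = 1e-4)
  bump <- function(t, tp, q) (t / tp)^q * exp(q * (1 - t / tp))
  bump(tt, 0.6 * tl, 4) - 0.6 * bump(tt, 1.3 * tl, 4)
}

chan_weights <- function(labels, strong, mid = character(0),
                         w = c(1, 0.6, 0.2)) {
  out <- rep(w[3], length(labels))
  out[labels %in% mid] <- w[2]
  out[labels %in% strong] <- w[1]
  out
}

#' Synthetic EEG trial
#'
#' Pink-noise background mixed across channels, plus (a) a biphasic
#' transient after every on and off transition of the gazed LED on
#' parieto-occipital channels, (b) in frequency mode a sinusoid at the
#' target frequency and its second harmonic on occipital channels, and
#' (c) a synchronized narrowband network source that appears in short random
#' bursts during rest and is sustained (scaled by
#' `covariance_shift_scale`) from `true_onset` to the end of the
#' stimulus, so the spatial covariance changes detectably at task onset.
#'
#' @param config a `synth_config`.
#' @param schedule a `stim_schedule` (its clock starts at `true_onset`).
#' @param target_led gazed LED, 1-4.
#' @param true_onset wall time of stimulus start, s.
#' @param window `c(t_start, t_end)` of the generated segment, s, around
#'   the nominal onset at 0.
#' @param subject_scale multiplicative subject amplitude effect.
#' @param latency_shift_ms additive subject latency effect.
#' @param seed RNG seed (defaults to the config seed).
#' @return An `mc_segment`, `t0 = window[1]`.
#' @export
synth_eeg_trial <- function(config, schedule, target_led, true_onset = 0,
                            window = c(-4, 8), subject_scale = 1,
                            latency_shift_ms = 0, seed = config$seed) {
  if (!target_led %in% 1:4) stop("target_led must be 1..4")
  set.seed(seed)
  rate <- config$eeg_rate
  labels <- config$eeg_channels
  C <- length(labels)
  n <- round((window[2] - window[1]) * rate)
  t <- window[1] + (seq_len(n) - 1) / rate
  stim_end <- true_onset + schedule$trial_s

  mix <- diag(C) + 0.15 * matrix(stats::rnorm(C * C), C)
  x <- mix %*% (config$noise_sd *
                  t(vapply(seq_len(C), function(i) pink_noise(n), numeric(n))))

  # synchronized network source: quasi-regular bursts at rest, suppressed
  # just before and after the task, sustained during the task
  if (config$sync_amplitude > 0) {
    src <- sin(2 * pi * config$sync_freq * t + stats::runif(1, 0, 2 * pi))
    env <- numeric(n)
    burst_len <- 0.4
    burst_regions <- rbind(c(window[1], true_onset - 0.6 - burst_len),
                           c(stim_end + 0.5, window[2] - burst_len))
    starts <- c()
    for (r in 1:2) {
      span <- burst_regions[r, 2] - burst_regions[r, 1]
      if (span <= 0) next
      grid <- seq(burst_regions[r, 1], burst_regions[r, 2],
                  by = 1 / config$rest_burst_rate)
      starts <- c(starts, grid + stats::runif(length(grid), -0.1, 0.1))
    }
    for (b in starts[starts >= window[1] & starts + burst_len <= window[2]]) {
      ramp <- 0.5 - 0.5 * cos(pi * pmin(1, pmax(0, (t - b) / 0.08)))
      fall <- 0.5 - 0.5 * cos(pi * pmin(1, pmax(0, (b + burst_len - t) / 0.08)))
      env <- pmax(env, ramp * fall)
    }
    task <- t >= true_onset + config$sync_task_delay & t < stim_end
    env[task] <- config$covariance_shift_scale
    g <- chan_weights(labels, c("O1", "O2", "Oz"), c("Pz", "P3", "P4"),
                      c(1, 0.7, 0.3))
    x <- x + config$sync_amplitude * subject_scale * outer(g, src * env)
  }

  # flash-locked transients at every transition of the gazed LED
  if (config$fvep_amplitude > 0) {
    lat <- config$fvep_latency + latency_shift_ms
    tr <- c(schedule$onsets[[target_led]], schedule$offsets[[target_led]])
    w <- chan_weights(labels, c("Pz", "O1", "O2"), c("P3", "P4"),
                      c(1, 0.6, 0.2))
    for (ev in tr) {
      rel <- t - (true_onset + ev)
      sel <- rel >= 0 & rel <= 0.35
      if (!any(sel)) next
      k <- fvep_kernel(rel[sel], lat)
      x[, sel] <- x[, sel] +
        config$fvep_amplitude * subject_scale * outer(w, k)
    }
  }

  # steady-state oscillation at the flicker frequency + 2nd harmonic
  if (config$ssvep_amplitude > 0 &&
      schedule$patterns[[target_led]]$mode == "frequency") {
    f <- schedule$patterns[[target_led]]$frequency
    occ <- chan_weights(labels, c("O1", "O2", "Oz"), c("Pz"), c(1, 0.5, 0))
    task <- t >= true_onset & t < stim_end
    ph <- stats::runif(2, 0, 2 * pi)
    osc <- (sin(2 * pi * f * t + ph[1]) +
              0.5 * sin(2 * pi * 2 * f * t + ph[2])) * as.numeric(task)
    x <- x + config$ssvep_amplitude * subject_scale * outer(occ, osc)
  }

  mc_segment(x, rate, labels, window[1])
}

#' Synthetic binocular pupil trial
#'
#' First-order constriction/redilation dynamics driven by the luminance of
#' the gazed LED after `plr_latency`: the diameter relaxes toward
#' `baseline - gain` while the LED is lit (fast time constant) and back to
#' baseline while dark (slow time constant). Slow hippus, per-eye noise and
#' blink dropouts (confidence < 0.6) are superimposed; the two eyes share
#' the drive but not the noise.
#'
#' @param config a `synth_config`.
#' @param schedule a `stim_schedule`.
#' @param gazed_led LED the subject gazes at, 1-4.
#' @param true_onset wall time of stimulus start, s.
#' @param window generated time range, s.
#' @param subject_scale multiplicative subject gain effect.
#' @param seed RNG seed.
#' @param tau_constrict,tau_redilate time constants, s.
#' @return A `pupil_trial` (see [pupil_trial()]), `t0 = window[1]`.
#' @export
synth_pupil_trial <- function(config, schedule, gazed_led, true_onset = 0,
                              window = c(-0.5, 6.5), subject_scale = 1,
                              seed = config$seed,
                              tau_constrict = 0.35, tau_redilate = 1.2) {
  if (!gazed_led %in% 1:4) stop("gazed_led must be 1..4")
  set.seed(derive_seed(seed, 17))
  rate <- config$pupil_rate
  n <- round((window[2] - window[1]) * rate)
  t <- window[1] + (seq_len(n) - 1) / rate
  dt <- 1 / rate
  lat <- config$plr_latency / 1000
  gain <- config$plr_constriction_gain * subject_scale
  lum <- led_luminance(schedule, gazed_led, t - true_onset - lat)
  lum[t < true_onset + lat] <- 0

  d0 <- config$baseline_mm
  hippus <- 0.04 * sin(2 * pi * 0.15 * t + stats::runif(1, 0, 2 * pi))
  drive <- numeric(n)
  drive[1] <- 0
  for (i in 2:n) {
    target <- -gain * lum[i]
    tau <- if (target < drive[i - 1]) tau_constrict else tau_redilate
    drive[i] <- drive[i - 1] + dt * (target - drive[i - 1]) / tau
  }

  one_eye <- function(gain_e) {
    d <- d0 + gain_e * drive + hippus + stats::rnorm(n, 0, 0.02)
    conf <- pmin(1, 0.9 + stats::rnorm(n, 0, 0.03))
    n_blink <- stats::rpois(1, config$blink_rate * (window[2] - window[1]) / 60)
    if (n_blink > 0) {
      for (b in stats::runif(n_blink, window[1], window[2] - 0.3)) {
        sel <- t >= b & t < b + 0.25
        conf[sel] <- stats::runif(sum(sel), 0.05, 0.3)
        d[sel] <- d[sel] - 1.5
      }
    }
    list(d = d, conf = conf)
  }
  left <- one_eye(1.03)
  right <- one_eye(0.97)
  pupil_trial(left$d, right$d, left$conf, right$conf, rate, window[1],
              target_led = gazed_led)
}

#' Synthetic temporal-muscle EMG
#'
#' Two channels (T3, T4) of band-limited (20-150 Hz) noise; with
#' `chewing = TRUE`, high-amplitude bursts at `chew_rate` with small timing
#' jitter are superimposed on both channels.
#'
#' @param config a `synth_config`.
#' @param chewing logical.
#' @param duration seconds.
#' @param chew_from time of first burst, s.
#' @param seed RNG seed.
#' @return An `mc_segment` with channels T3, T4 at `eeg_rate`.
#' @export
synth_emg <- function(config, chewing, duration, chew_from = 0.3,
                      seed = config$seed) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(derive_seed(seed, 29))
  rate <- config$eeg_rate
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  flt <- signal::butter(4, c(20, min(150, rate / 2 - 1)) / (rate / 2), "pass")
  base <- function() {
    x <- signal::filtfilt(flt, stats::rnorm(n))
    x / stats::sd(x) * config$emg_noise_sd
  }
  x <- rbind(T3 = base(), T4 = base())
  if (chewing) {
    centers <- seq(chew_from, duration - 0.1, by = 1 / config$chew_rate)
    centers <- centers + stats::rnorm(length(centers), 0, 0.03)
    env <- numeric(n)
    for (b in centers) {
      sel <- t >= b & t < b + 0.3
      env[sel] <- env[sel] + sin(pi * (t[sel] - b) / 0.3)^2
    }
    burst <- signal::filtfilt(flt, stats::rnorm(n))
    burst <- burst / stats::sd(burst) * config$emg_noise_sd * 8
    x <- x + rbind(burst * env, burst * env)
  }
  mc_segment(x, rate, c("T3", "T4"), 0)
}

#' Synthetic multi-subject dataset
#'
#' Per subject: `n_trials` trials with balanced, randomized LED targets and
#' log-normal amplitude / Gaussian latency subject effects (the
#' between-subject variability that motivates subject-independent
#' validation). Stimulus onsets are at the cue (0) unless
#' `onset_jitter_sd > 0`.
#'
#' @param config a `synth_config`.
#' @param mode schedule mode, `"pattern"` or `"frequency"`.
#' @param modalities subset of `c("eeg", "pupil")` to generate.
#' @param eeg_window,pupil_window generated time ranges, s.
#' @return list of class `synth_dataset`: `config`, `schedule`, `subjects`
#'   (list of lists of trials; each trial has `eeg`, `pupil`, `target_led`,
#'   `true_onset`, `subject`).
#' @export
synth_dataset <- function(config, mode = c("pattern", "frequency"),
                          modalities = c("eeg", "pupil"),
                          eeg_window = c(-4, 8), pupil_window = c(-0.5, 6.5)) {
  mode <- match.arg(mode)
  schedule <- build_default_schedule(mode)
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, 1000 + s))
    amp <- stats::rlnorm(1, 0, 0.2)
    lat_shift <- stats::rnorm(1, 0, 8)
    targets <- sample(rep(1:4, length.out = config$n_trials))
    onsets <- if (config$onset_jitter_sd > 0) {
      stats::rnorm(config$n_trials, 0, config$onset_jitter_sd)
    } else rep(0, config$n_trials)
    trials <- vector("list", config$n_trials)
    for (k in seq_len(config$n_trials)) {
      sd_k <- derive_seed(config$seed, s, k)
      trial <- list(target_led = targets[k], true_onset = onsets[k],
                    subject = s)
      if ("eeg" %in% modalities) {
        trial$eeg <- synth_eeg_trial(config, schedule, targets[k],
                                     true_onset = onsets[k],
                                     window = eeg_window,
                                     subject_scale = amp,
                                     latency_shift_ms = lat_shift,
                                     seed = sd_k)
      }
      if ("pupil" %in% modalities) {
        trial$pupil <- synth_pupil_trial(config, schedule, targets[k],
                                         true_onset = onsets[k],
                                         window = pupil_window,
                                         subject_scale = amp,
                                         seed = sd_k)
      }
      trials[[k]] <- trial
    }
    subjects[[s]] <- trials
  }
  structure(list(config = config, schedule = schedule, mode = mode,
                 subjects = subjects),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d subjects x %d trials, %s mode\n",
              length(x$subjects), length(x$subjects[[1]]), x$mode))
  invisible(x)
}
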