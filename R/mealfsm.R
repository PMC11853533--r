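#' Pupil start trigger for the meal cycle
#'
#' While the robot is in standby only LED 4 is lit; a user who gazes at it
#' holds a sustained constriction. The trigger fires when the normalized
#' diameter stays below `1 - drop` for at least `gaze_hold` contiguous
#' seconds.
#'
#' @param pupil a normalized `pupil_trial`.
#' @param gaze_hold required hold, s.
#' @param drop fractional constriction depth required.
#' @return list `(kind = "plr_start", time)` or `NULL`.
#' @export
plr_start_trigger <- function(pupil, gaze_hold = 4.5, drop = 0.05) {
  d <- (pupil$left + pupil$right) / 2
  below <- d < (1 - drop)
  need <- ceiling(gaze_hold * pupil$rate)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= need) {
      fire_idx <- ends[i] - r$lengths[i] + need
      return(list(kind = "plr_start",
                  time = pupil$t0 + (fire_idx - 1) / pupil$rate))
    }
  }
  NULL
}

#' EMG chewing trigger
#'
#' Band-pass, rectify, smooth: fires at the first envelope crossing of
#' `baseline mean + k * baseline SD` sustained for `sustain` seconds on
#' either temporal channel.
#'
#' @param emg a 2-channel `mc_segment` (T3, T4).
#' @param band band-pass corners, Hz.
#' @param k threshold in baseline SDs.
#' @param sustain required supra-threshold duration, s.
#' @param baseline_s initial span used to estimate the resting envelope.
#' @param smooth_s envelope smoothing window, s.
#' @return list `(kind = "emg_chew", time)` or `NULL`.
#' @export
emg_chew_trigger <- function(emg, band = c(20, 124), k = 5, sustain = 0.15,
                             baseline_s = 1, smooth_s = 0.1) {
  if (!is.finite(k)) return(NULL)
  filt <- bandpass(emg, band[1], min(band[2], emg$rate / 2 - 1),
                   "butterworth", 4)
  w <- max(1L, round(smooth_s * emg$rate))
  kern <- rep(1 / w, w)
  env <- apply(abs(filt$samples), 1, function(x) {
    as.numeric(stats::filter(x, kern, sides = 2))
  })
  env <- rowMeans(env, na.rm = TRUE)  # averaged T3/T4 envelope
  nb <- round(baseline_s * emg$rate)
  base <- env[seq_len(nb)]
  thr <- mean(base, na.rm = TRUE) + k * stats::sd(base[!is.na(base)])
  above <- !is.na(env) & env > thr
  need <- ceiling(sustain * emg$rate)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= need) {
      idx <- ends[i] - r$lengths[i] + 1L
      return(list(kind = "emg_chew", time = emg$t0 + (idx - 1) / emg$rate))
    }
  }
  NULL
}

meal_states <- c("STANDBY", "PLR_CONFIRMED", "FLICKER", "SELECTING",
                 "GRAB", "LIFTED", "LOWERING")

#' Create a meal-cycle state machine
#'
#' The seven-step cycle: STANDBY (LED 4 lit, pupil trigger armed) ->
#' PLR_CONFIRMED (LED 4 off, 2 s wait) -> FLICKER (4.5 s selection
#' stimulus) -> SELECTING (decode) -> GRAB -> LIFTED (EMG trigger armed;
#' safety timeout 10 s) -> LOWERING -> STANDBY. The pupil trigger is armed
#' only in STANDBY and the chew trigger only in LIFTED; any other event is
#' ignored and logged, never fatal.
#'
#' @param confirm_wait_s wait between pupil confirmation and flicker.
#' @param flicker_s flicker duration.
#' @param lift_timeout_s safety timeout in LIFTED.
#' @return list of class `meal_fsm`.
#' @export
meal_fsm <- function(confirm_wait_s = 2, flicker_s = 4.5,
                     lift_timeout_s = 10) {
  structure(list(state = "STANDBY", since = 0,
                 confirm_wait_s = confirm_wait_s, flicker_s = flicker_s,
                 lift_timeout_s = lift_timeout_s,
                 log = data.frame(time = numeric(0), event = character(0),
                                  state = character(0),
                                  command = character(0))),
            class = "meal_fsm")
}

fsm_emit <- function(fsm, time, event, new_state, command) {
  fsm$log <- rbind(fsm$log, data.frame(time = time, event = event,
                                       state = new_state, command = command))
  if (!is.na(new_state) && new_state != fsm$state) {
    fsm$state <- new_state
    fsm$since <- time
  }
  fsm
}

#' Advance the meal-cycle state machine
#'
#' @param fsm a `meal_fsm`.
#' @param event list with `kind` (`"plr_start"`, `"emg_chew"`, `"decoded"`
#'   with `led`, or `"tick"`) and `time` (s, monotone).
#' @return the updated `meal_fsm`; emitted robot commands accumulate in
#'   `fsm$log`.
#' @export
fsm_step <- function(fsm, event) {
  kind <- event$kind
  time <- event$time
  s <- fsm$state
  el <- time - fsm$since
  if (kind == "plr_start") {
    if (s == "STANDBY") {
      return(fsm_emit(fsm, time, kind, "PLR_CONFIRMED", "led4_off"))
    }
    return(fsm_emit(fsm, time, paste0(kind, " (ignored: unarmed)"), NA, ""))
  }
  if (kind == "emg_chew") {
    if (s == "LIFTED") {
      return(fsm_emit(fsm, time, kind, "LOWERING", "spoon_lower"))
    }
    return(fsm_emit(fsm, time, paste0(kind, " (ignored: unarmed)"), NA, ""))
  }
  if (kind == "decoded") {
    if (s == "SELECTING") {
      return(fsm_emit(fsm, time, kind, "GRAB",
                      paste0("grab_move_led", event$led)))
    }
    return(fsm_emit(fsm, time, paste0(kind, " (ignored)"), NA, ""))
  }
  if (kind == "tick") {
    if (s == "PLR_CONFIRMED" && el >= fsm$confirm_wait_s) {
      return(fsm_emit(fsm, time, kind, "FLICKER", "leds_flicker"))
    }
    if (s == "FLICKER" && el >= fsm$flicker_s) {
      return(fsm_emit(fsm, time, kind, "SELECTING", "decode"))
    }
    if (s == "GRAB") {
      return(fsm_emit(fsm, time, kind, "LIFTED", "spoon_lift"))
    }
    if (s == "LIFTED" && el >= fsm$lift_timeout_s) {
      return(fsm_emit(fsm, time, kind, "LOWERING", "spoon_lower (timeout)"))
    }
    if (s == "LOWERING") {
      return(fsm_emit(fsm, time, kind, "STANDBY", "led4_on"))
    }
    return(fsm)
  }
  fsm_emit(fsm, time, paste0(kind, " (unknown, ignored)"), NA, "")
}

#' Replay an event tape through the state machine
#'
#' @param fsm a `meal_fsm`.
#' @param events data.frame with columns `time`, `kind` and optionally
#'   `led`, ordered by time; tick events are interleaved automatically at
#'   `tick_dt` resolution up to `until`.
#' @param tick_dt clock resolution, s.
#' @param until final time, s.
#' @return the final `meal_fsm` (with the full `log`).
#' @export
fsm_run <- function(fsm, events, tick_dt = 0.1, until = NULL) {
  if (is.null(until)) until <- max(c(events$time, 0)) + 15
  ticks <- data.frame(time = seq(0, until, by = tick_dt), kind = "tick")
  tape <- rbind(events[, c("time", "kind")], ticks)
  tape <- tape[order(tape$time, tape$kind != "tick"), ]
  leds <- if ("led" %in% names(events)) events$led else NULL
  for (i in seq_len(nrow(tape))) {
    ev <- list(kind = tape$kind[i], time = tape$time[i])
    if (ev$kind == "decoded") {
      j <- which(events$kind == "decoded" & events$time == ev$time)[1]
      ev$led <- if (!is.null(leds)) leds[j] else 1
    }
    fsm <- fsm_step(fsm, ev)
  }
  fsm
}
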