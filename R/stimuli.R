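#' LED pattern definition
#'
#' One LED of the four-target stimulus board. In `"frequency"` mode the LED
#' flickers as a 50% duty-cycle square wave at `frequency` Hz for the whole
#' trial; in `"pattern"` mode it alternates `on_ms` lit / `off_ms` dark,
#' optionally starting after `start_delay_ms` and optionally going dark for
#' the remainder of the trial at `full_off_ms` (measured from trial start —
#' both delayed and non-delayed LEDs share the trial clock).
#'
#' @param led_id integer 1-4.
#' @param mode `"frequency"` or `"pattern"`.
#' @param frequency flicker frequency in Hz (frequency mode only).
#' @param start_delay_ms delay before the first onset, ms.
#' @param on_ms,off_ms lit/dark phase durations, ms (pattern mode).
#' @param full_off_ms time after trial start at which the LED goes dark for
#'   the remainder of the trial, ms, or `NULL`.
#' @param trial_ms trial (stimulus) length, ms.
#' @return An object of class `led_pattern`.
#' @export
led_pattern <- function(led_id, mode = c("pattern", "frequency"),
                        frequency = NULL, start_delay_ms = 0,
                        on_ms = NULL, off_ms = NULL,
                        full_off_ms = NULL, trial_ms = 5000) {
  mode <- match.arg(mode)
  if (!led_id %in% 1:4) stop("led_id must be 1, 2, 3 or 4")
  if (start_delay_ms < 0) stop("start_delay_ms must be >= 0")
  if (!is.null(full_off_ms) && full_off_ms > trial_ms) {
    stop("full_off_ms must not exceed trial_ms")
  }
  if (mode == "pattern") {
    if (is.null(on_ms) || is.null(off_ms) || on_ms <= 0 || off_ms <= 0) {
      stop("pattern mode needs on_ms > 0 and off_ms > 0")
    }
  } else {
    if (is.null(frequency) || frequency <= 0) {
      stop("frequency mode needs frequency > 0")
    }
  }
  structure(list(led_id = led_id, mode = mode, frequency = frequency,
                 start_delay_ms = start_delay_ms, on_ms = on_ms,
                 off_ms = off_ms, full_off_ms = full_off_ms,
                 trial_ms = trial_ms),
            class = "led_pattern")
}

enumerate_transitions <- function(p) {
  end_s <- p$trial_ms / 1000
  cutoff <- if (is.null(p$full_off_ms)) end_s else p$full_off_ms / 1000
  onsets <- numeric(0)
  offsets <- numeric(0)
  if (p$mode == "pattern") {
    period_ms <- p$on_ms + p$off_ms
    k <- 0
    repeat {
      on_t <- (p$start_delay_ms + k * period_ms) / 1000
      if (on_t >= cutoff || on_t >= end_s) break
      off_t <- on_t + p$on_ms / 1000
      # an on-phase truncated by the cutoff still darkens: record the
      # forced offset at the cutoff so offset-locked epochs see it
      off_t <- min(off_t, cutoff, end_s)
      onsets <- c(onsets, on_t)
      offsets <- c(offsets, off_t)
      k <- k + 1
    }
  } else {
    period <- 1 / p$frequency
    k <- 0
    repeat {
      on_t <- p$start_delay_ms / 1000 + k * period
      if (on_t >= cutoff || on_t >= end_s) break
      off_t <- min(on_t + period / 2, cutoff, end_s)
      onsets <- c(onsets, on_t)
      offsets <- c(offsets, off_t)
      k <- k + 1
    }
  }
  list(onsets = onsets, offsets = offsets)
}

#' Four-LED stimulus schedule
#'
#' @param patterns list of four `led_pattern` objects, led_id 1-4 in order.
#' @return An object of class `stim_schedule` with per-LED on/off transition
#'   times (seconds, trial clock).
#' @export
stim_schedule <- function(patterns) {
  if (length(patterns) != 4L ||
      !all(vapply(patterns, inherits, TRUE, "led_pattern")) ||
      !identical(vapply(patterns, `[[`, 0, "led_id"), as.numeric(1:4))) {
    stop("patterns must be a list of four led_pattern objects with led_id 1..4")
  }
  tr <- lapply(patterns, enumerate_transitions)
  structure(list(patterns = patterns,
                 onsets = lapply(tr, `[[`, "onsets"),
                 offsets = lapply(tr, `[[`, "offsets"),
                 trial_s = patterns[[1]]$trial_ms / 1000),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %s mode, trial %g s\n",
              x$patterns[[1]]$mode, x$trial_s))
  for (k in 1:4) {
    cat(sprintf("  LED%d: %d onsets, %d offsets\n", k,
                length(x$onsets[[k]]), length(x$offsets[[k]])))
  }
  invisible(x)
}

#' Default stimulus schedules
#'
#' `"pattern"` mode is the pupil-driving board: LED1 0 ms delay, 500/500 ms;
#' LED2 500 ms delay, 350/350 ms, dark from 2500 ms; LED3 500 ms delay,
#' 450/450 ms; LED4 0 ms delay, 400/400 ms, dark from 2500 ms.
#' `"frequency"` mode is the steady-state bank 6.6, 7.5, 8.57 and 10 Hz,
#' flickering for the whole 5 s trial.
#'
#' @param mode `"pattern"` or `"frequency"`.
#' @param trial_ms trial length, ms.
#' @return A `stim_schedule`.
#' @export
build_default_schedule <- function(mode = c("pattern", "frequency"),
                                   trial_ms = 5000) {
  mode <- match.arg(mode)
  if (mode == "pattern") {
    stim_schedule(list(
      led_pattern(1, "pattern", start_delay_ms = 0,   on_ms = 500, off_ms = 500, trial_ms = trial_ms),
      led_pattern(2, "pattern", start_delay_ms = 500, on_ms = 350, off_ms = 350, full_off_ms = 2500, trial_ms = trial_ms),
      led_pattern(3, "pattern", start_delay_ms = 500, on_ms = 450, off_ms = 450, trial_ms = trial_ms),
      led_pattern(4, "pattern", start_delay_ms = 0,   on_ms = 400, off_ms = 400, full_off_ms = 2500, trial_ms = trial_ms)))
  } else {
    freqs <- c(6.6, 7.5, 8.57, 10)
    stim_schedule(lapply(1:4, function(k) {
      led_pattern(k, "frequency", frequency = freqs[k], trial_ms = trial_ms)
    }))
  }
}

#' Transitions of one LED inside a time window
#'
#' @param schedule a `stim_schedule`.
#' @param led integer 1-4.
#' @param t0,t1 window bounds in seconds; half-open `[t0, t1)`.
#' @return list with `onsets` and `offsets` (seconds, ordered).
#' @export
transitions_in_window <- function(schedule, led, t0, t1) {
  if (!led %in% 1:4) stop("led must be 1, 2, 3 or 4")
  on <- schedule$onsets[[led]]
  off <- schedule$offsets[[led]]
  list(onsets = on[on >= t0 & on < t1], offsets = off[off >= t0 & off < t1])
}

#' Binary luminance of one LED
#'
#' @param schedule a `stim_schedule`.
#' @param led integer 1-4.
#' @param t numeric vector of times (seconds, trial clock).
#' @return 0/1 vector: 1 while the LED is lit.
#' @export
led_luminance <- function(schedule, led, t) {
  if (!led %in% 1:4) stop("led must be 1, 2, 3 or 4")
  on <- schedule$onsets[[led]]
  off <- schedule$offsets[[led]]
  out <- numeric(length(t))
  for (i in seq_along(on)) out <- out + as.numeric(t >= on[i] & t < off[i])
  pmin(out, 1)
}

#' Flatten a schedule to an event table
#'
#' @param schedule a `stim_schedule`.
#' @return data.frame with columns `time_s`, `led_id`,
#'   `transition` (`"on"`/`"off"`), ordered by time.
#' @export
schedule_events <- function(schedule) {
  rows <- do.call(rbind, lapply(1:4, function(k) {
    rbind(
      if (length(schedule$onsets[[k]]))
        data.frame(time_s = schedule$onsets[[k]], led_id = k, transition = "on"),
      if (length(schedule$offsets[[k]]))
        data.frame(time_s = schedule$offsets[[k]], led_id = k, transition = "off"))
  }))
  rows[order(rows$time_s, rows$led_id, rows$transition), , drop = FALSE]
}
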