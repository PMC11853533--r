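#' Binocular pupil trial
#'
#' Left/right pupil-diameter series (mm) on a common sampling grid with
#' per-sample detection confidence in [0, 1].
#'
#' @param left,right diameter series, mm.
#' @param conf_left,conf_right per-sample confidence; default 1.
#' @param rate sampling rate, Hz (30 for the eyewear cameras).
#' @param t0 time of the first sample, s (trial clock).
#' @param target_led ground-truth LED (1-4) or `NA`.
#' @return An object of class `pupil_trial`.
#' @export
pupil_trial <- function(left, right, conf_left = rep(1, length(left)),
                        conf_right = rep(1, length(right)),
                        rate = 30, t0 = 0, target_led = NA) {
  if (length(left) != length(right)) stop("left/right lengths differ")
  if (length(conf_left) != length(left) || length(conf_right) != length(right)) {
    stop("confidence length must match the series")
  }
  structure(list(left = left, right = right,
                 conf_left = pmin(1, pmax(0, conf_left)),
                 conf_right = pmin(1, pmax(0, conf_right)),
                 rate = rate, t0 = t0, target_led = target_led),
            class = "pupil_trial")
}

#' @export
print.pupil_trial <- function(x, ...) {
  cat(sprintf("<pupil_trial> %d samples @ %g Hz, t0 = %.3f s, target = %s\n",
              length(x$left), x$rate, x$t0,
              ifelse(is.na(x$target_led), "?", x$target_led)))
  invisible(x)
}

#' Cut a pupil trial to a time window
#'
#' Half-open `[from, to)` on the sample grid.
#'
#' @param trial a `pupil_trial`.
#' @param from,to bounds, s (trial clock).
#' @return A `pupil_trial`.
#' @export
crop_pupil <- function(trial, from, to) {
  i0 <- round((from - trial$t0) * trial$rate) + 1
  i1 <- round((to - trial$t0) * trial$rate)
  if (i0 < 1 || i1 > length(trial$left) || i1 <= i0) {
    stop("window [", from, ", ", to, ") outside pupil trial")
  }
  idx <- i0:i1
  pupil_trial(trial$left[idx], trial$right[idx],
              trial$conf_left[idx], trial$conf_right[idx],
              trial$rate, trial$t0 + (i0 - 1) / trial$rate, trial$target_led)
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Reject low-quality pupil trials
#'
#' A trial is rejected when either eye has a contiguous run of confidence
#' below `confidence_floor` longer than `max_gap` seconds, or more than
#' `max_low_fraction` low-confidence samples overall (the automated
#' counterpart of visual blink/artifact screening).
#'
#' @param trials list of `pupil_trial`.
#' @param confidence_floor confidence threshold.
#' @param max_gap longest tolerated low-confidence run, s.
#' @param max_low_fraction tolerated overall low-confidence fraction.
#' @return list with `kept`, `rejected` (lists of trials) and counts
#'   `n_kept`, `n_rejected`.
#' @export
reject_invalid_trials <- function(trials, confidence_floor = 0.6,
                                  max_gap = 0.5, max_low_fraction = 0.25) {
  if (confidence_floor < 0 || confidence_floor > 1) {
    stop("confidence_floor must be in [0, 1]")
  }
  bad <- vapply(trials, function(tr) {
    for (eye in list(tr$conf_left, tr$conf_right)) {
      low <- eye < confidence_floor
      if (longest_run(low) / tr$rate > max_gap) return(TRUE)
      if (mean(low) > max_low_fraction) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(kept = trials[!bad], rejected = trials[bad],
       n_kept = sum(!bad), n_rejected = sum(bad))
}

interp_low_confidence <- function(x, conf, floor = 0.6) {
  low <- conf < floor
  if (!any(low) || all(low)) return(x)
  idx <- seq_along(x)
  stats::approx(idx[!low], x[!low], xout = idx, rule = 2)$y
}

#' Baseline-normalize a pupil trial
#'
#' Short low-confidence gaps are linearly interpolated, then each eye is
#' divided by its own mean over the first `baseline_s` seconds, so the
#' series starts at ~1 and constriction reads as a fractional drop.
#'
#' @param trial a `pupil_trial`.
#' @param baseline_s baseline span, s.
#' @param confidence_floor samples below this are interpolated first.
#' @return The normalized `pupil_trial`.
#' @export
normalize_pupil <- function(trial, baseline_s = 0.5, confidence_floor = 0.6) {
  nb <- max(1L, round(baseline_s * trial$rate))
  l <- interp_low_confidence(trial$left, trial$conf_left, confidence_floor)
  r <- interp_low_confidence(trial$right, trial$conf_right, confidence_floor)
  bl <- mean(l[seq_len(min(nb, length(l)))])
  br <- mean(r[seq_len(min(nb, length(r)))])
  if (bl <= 0 || br <= 0) stop("non-positive pupil baseline")
  out <- pupil_trial(l / bl, r / br, trial$conf_left, trial$conf_right,
                     trial$rate, trial$t0, trial$target_led)
  out$normalized <- TRUE
  out
}
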