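#' Blend pupil probabilities with flash-response margins
#'
#' Softmax-normalizes the four SVM margins and mixes them with the pupil
#' classifier's probabilities: `weight * plr + (1 - weight) * fvep`.
#' The default weight 1 keeps the pupil decision and uses the EEG stream
#' only for onset correction and trial validity.
#'
#' @param plr_probs pupil class probabilities (4-vector).
#' @param fvep_margins signed SVM margins (4-vector).
#' @param weight mixing weight in [0, 1].
#' @return probability 4-vector summing to 1.
#' @export
fuse <- function(plr_probs, fvep_margins, weight = 1) {
  if (any(!is.finite(plr_probs)) || any(!is.finite(fvep_margins))) {
    stop("fuse needs finite inputs")
  }
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  m <- fvep_margins - max(fvep_margins)
  soft <- exp(m) / sum(exp(m))
  p <- weight * plr_probs + (1 - weight) * soft
  p / sum(p)
}

#' Decode one hybrid trial
#'
#' The full single-trial pipeline: (1) band-pass the dry EEG (0.7-54 Hz),
#' take GFP troughs, build the entropy-selected reference covariance from
#' the latter half of the pre-stimulus epoch, compute the dynamic
#' Riemannian distance over the stimulus epoch and detect the task onset;
#' (2) if the detected shift fails the consistency check, adjust the
#' index against the pupil trace: the first sustained constriction bounds
#' the admissible onset (the stimulus can precede it by at most the
#' largest LED start delay plus the reflex latency), so the EEG index is
#' clamped into that interval; (3) re-epoch the pupil series to 0-4.5 s
#' from the final onset, normalize, extract wavelet features and classify
#' with the pupil TCN; (4) optionally compute flash-response margins on
#' the re-epoched EEG and fuse; (5) a trial with no detected shift is
#' excluded.
#'
#' @param eeg full-trial `mc_segment` covering at least
#'   `ref_epoch[1]`..`target_epoch[2]` s around the nominal onset 0.
#' @param pupil the trial's `pupil_trial`.
#' @param schedule the `stim_schedule`.
#' @param plr_model trained `tcn_model`.
#' @param fvep_models optional `fvep_models`; `NULL` for pupil-only.
#' @param fusion_weight passed to [fuse()] when FVEP models are given.
#' @param ref_epoch,target_epoch reference and target ranges, s relative
#'   to the nominal onset.
#' @param scan_lookback extra pre-onset context prepended to the
#'   detection scan, s; at least one covariance-window length is needed
#'   for the transition to be interior to the scanned series.
#' @param window_troughs troughs per covariance window.
#' @param band band-pass corners for the hybrid EEG, Hz.
#' @param neural_delay assumed lag between stimulus onset and the
#'   detected brain-state transition, s; subtracted from the detected
#'   time to estimate the stimulus onset.
#' @param tensor_args extra arguments to [cwt_features()] (to match the
#'   model's input shape).
#' @param trial_id identifier carried into the result.
#' @return list of class `decoding_result`: `trial_id`, `predicted_led`,
#'   `probabilities`, `source` ("plr" or "fused"), `onset`
#'   (`onset_decision`), `onset_time`, `excluded`.
#' @export
decode_trial <- function(eeg, pupil, schedule, plr_model,
                         fvep_models = NULL, fusion_weight = 1,
                         ref_epoch = c(-3, 0), target_epoch = c(0, 5),
                         window_troughs = 35, band = c(0.7, 54),
                         neural_delay = 0.3, scan_lookback = 0.6,
                         tensor_args = list(), trial_id = NA) {
  if (is.null(plr_model)) stop("decode_trial needs a trained PLR model")
  filt <- bandpass(eeg, band[1], band[2], "butterworth", 3)

  ref_half <- c(mean(ref_epoch), ref_epoch[2])
  ref_seg <- crop_segment(filt, ref_half[1], ref_half[2])
  ref_cand <- sliding_covariances(ref_seg, gfp(ref_seg), window_troughs)
  sigma_ref <- reference_matrix(ref_cand$matrices)

  tgt_seg <- crop_segment(filt, target_epoch[1] - scan_lookback,
                          target_epoch[2])
  series <- distance_series(tgt_seg, sigma_ref, gfp(tgt_seg), window_troughs)
  onset <- detect_onset(series)

  if (onset$excluded) {
    return(structure(list(trial_id = trial_id, predicted_led = NA_integer_,
                          probabilities = NULL, source = NA_character_,
                          onset = onset, onset_time = NA_real_,
                          excluded = TRUE),
                     class = "decoding_result"))
  }
  onset_time <- onset$detected_time - neural_delay
  if (onset$adjusted_by_plr) {
    t_plr <- plr_fallback_onset(normalize_pupil(crop_pupil(
      pupil, pupil$t0, pupil$t0 + length(pupil$left) / pupil$rate)),
      expected_start = target_epoch[1] - scan_lookback)
    if (!is.na(t_plr)) {
      # the gazed LED's first on-phase starts 0..max_delay after stimulus
      # onset, so the constriction-implied onset bounds the EEG index
      max_delay <- max(vapply(schedule$patterns, `[[`, 0, "start_delay_ms")) / 1000
      onset_time <- min(max(onset_time, t_plr - max_delay - 0.05), t_plr)
    }
  }
  # clamp so the 4.5 s pupil window stays inside the recorded trace
  t_max <- pupil$t0 + length(pupil$left) / pupil$rate - 4.5
  onset_time <- min(max(onset_time, pupil$t0), t_max)

  pw <- crop_pupil(pupil, onset_time, onset_time + 4.5)
  tensor <- do.call(cwt_features, c(list(normalize_pupil(pw)), tensor_args))
  plr <- classify_plr(plr_model, tensor)
  probs <- plr$probabilities
  source <- "plr"
  if (!is.null(fvep_models)) {
    feats <- extract_trial_features(bandpass(eeg, 2, 30, "butterworth", 3),
                                    schedule, stim_onset = onset_time)
    margins <- combine_decisions(fvep_models, feats)$margins
    probs <- fuse(plr$probabilities, margins, fusion_weight)
    source <- "fused"
  }
  structure(list(trial_id = trial_id, predicted_led = which.max(probs),
                 probabilities = probs, source = source, onset = onset,
                 onset_time = onset_time, excluded = FALSE),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  if (x$excluded) {
    cat("<decoding_result> excluded\n")
  } else {
    cat(sprintf("<decoding_result> LED %d (%s, onset %.3f s)\n",
                x$predicted_led, x$source, x$onset_time))
  }
  invisible(x)
}

#' Summarize a set of decoding results
#'
#' @param results list of `decoding_result`.
#' @param truth integer vector of true LEDs (same length).
#' @param strict count excluded trials as errors instead of dropping them
#'   from the denominator.
#' @return list with `accuracy`, `n_scored`, `n_excluded`.
#' @export
score_decoding <- function(results, truth, strict = FALSE) {
  excl <- vapply(results, `[[`, TRUE, "excluded")
  pred <- vapply(results, function(r) {
    if (r$excluded) NA_real_ else as.numeric(r$predicted_led)
  }, numeric(1))
  hits <- sum(pred == truth, na.rm = TRUE)
  denom <- if (strict) length(results) else sum(!excl)
  list(accuracy = if (denom > 0) hits / denom else NA_real_,
       n_scored = denom, n_excluded = sum(excl))
}
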