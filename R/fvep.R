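#' Transition-locked averaged flash evoked potential
#'
#' Epochs the EEG from 100 ms before to 350 ms after every onset (or
#' offset) of one LED and averages the epochs sample-wise. The input
#' should already be band-passed (2-30 Hz) and restricted to the
#' parieto-occipital channels.
#'
#' @param eeg an `mc_segment` whose clock matches the schedule clock
#'   shifted by `stim_onset`.
#' @param schedule a `stim_schedule`.
#' @param led LED id 1-4.
#' @param transition `"onset"` or `"offset"`.
#' @param stim_onset wall time of stimulus start on the EEG clock, s.
#' @param window_ms epoch window around each transition.
#' @param channels channels to keep; `NULL` keeps all present.
#' @return An `mc_segment` (the average epoch, `t0 = window_ms[1]/1000`)
#'   with attribute `n_epochs`.
#' @export
averaged_fvep <- function(eeg, schedule, led, transition = c("onset", "offset"),
                          stim_onset = 0, window_ms = c(-100, 350),
                          channels = c("Pz", "O1", "O2")) {
  transition <- match.arg(transition)
  if (!is.null(channels)) {
    channels <- intersect(channels, eeg$channel_labels)
    if (!length(channels)) stop("none of the requested channels present")
    eeg <- select_channels(eeg, channels)
  }
  events <- if (transition == "onset") schedule$onsets[[led]] else schedule$offsets[[led]]
  ep <- suppressWarnings(epoch(eeg, events + stim_onset, window_ms))
  if (!length(ep$epochs)) {
    stop("no usable ", transition, " epochs for LED ", led,
         " (", ep$n_dropped, " dropped at segment edges)")
  }
  avg <- Reduce(`+`, lapply(ep$epochs, as.matrix)) / length(ep$epochs)
  out <- mc_segment(avg, eeg$rate, eeg$channel_labels, window_ms[1] / 1000)
  attr(out, "n_epochs") <- length(ep$epochs)
  out
}

#' Peak-to-valley amplitude of an averaged response
#'
#' Max minus min of the channel-averaged waveform inside the
#' post-transition search window.
#'
#' @param avg averaged epoch from [averaged_fvep()] (`t0` = epoch start
#'   relative to the transition).
#' @param search_window_ms window relative to the transition, ms.
#' @return scalar amplitude (uV), >= 0.
#' @export
peak_to_valley <- function(avg, search_window_ms = c(0, 350)) {
  t_ms <- segment_times(avg) * 1000
  sel <- t_ms >= search_window_ms[1] & t_ms < search_window_ms[2]
  if (!any(sel)) stop("empty peak-to-valley search window")
  w <- colMeans(avg$samples)[sel]
  max(w) - min(w)
}

#' Per-LED flash-response features of one trial
#'
#' For each of the four LEDs (regardless of the true target) the trial's
#' EEG is epoched on that LED's own transition times and the averaged
#' onset and offset responses are reduced to peak-to-valley amplitudes:
#' a 4 x 2 feature matrix per trial. Only the gazed LED's flicker times
#' line up with the evoked transients, so its row dominates.
#'
#' @param eeg full-trial `mc_segment` (band-passed).
#' @param schedule a `stim_schedule`.
#' @param stim_onset wall time of stimulus start, s.
#' @param channels channels used.
#' @return matrix of class `fvep_features`, rows LED1..4, columns
#'   `onset_p2v`, `offset_p2v`; attribute `n_epochs` (4 x 2 counts).
#' @export
extract_trial_features <- function(eeg, schedule, stim_onset = 0,
                                   channels = c("Pz", "O1", "O2")) {
  out <- matrix(NA_real_, 4, 2,
                dimnames = list(paste0("led", 1:4), c("onset_p2v", "offset_p2v")))
  cnt <- matrix(0L, 4, 2)
  for (k in 1:4) {
    for (j in 1:2) {
      tr <- c("onset", "offset")[j]
      avg <- averaged_fvep(eeg, schedule, k, tr, stim_onset,
                           channels = channels)
      out[k, j] <- peak_to_valley(avg)
      cnt[k, j] <- attr(avg, "n_epochs")
    }
  }
  structure(out, class = c("fvep_features", "matrix", "array"),
            n_epochs = cnt)
}

svm_margins <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the decision value toward the first factor level;
  # flip so positive margin always means "target"
  if (colnames(dv)[1] == "FALSE/TRUE") -dv[, 1] else dv[, 1]
}

#' Train the four per-LED binary SVMs
#'
#' One RBF support vector machine per LED, trained on that LED's
#' (onset, offset) peak-to-valley pair with label "this LED was the
#' target". Hyper-parameters are chosen by seeded stratified k-fold grid
#' search.
#'
#' @param features list of `fvep_features` (one per trial).
#' @param labels integer target LED per trial.
#' @param cost_grid,gamma_factors grid-search values; gamma values are
#'   `gamma_factors / (2 * mean feature variance)`.
#' @param k_folds internal cross-validation folds.
#' @param seed RNG seed for the folds.
#' @return list of class `fvep_models` with one entry per LED: the fitted
#'   svm, the searched grid and the selected point with its CV score.
#' @export
train_led_models <- function(features, labels,
                             cost_grid = c(0.1, 1, 10, 100),
                             gamma_factors = c(0.1, 1, 10),
                             k_folds = 5, seed = 1L) {
  labels <- as.integer(labels)
  models <- vector("list", 4)
  for (k in 1:4) {
    x <- t(vapply(features, function(f) unclass(f)[k, ], numeric(2)))
    y <- factor(labels == k, levels = c(FALSE, TRUE))
    if (length(unique(y)) < 2L) {
      stop("LED ", k, " has a single class; cannot train its binary model")
    }
    gamma0 <- 1 / (2 * mean(apply(x, 2, stats::var)))
    grid <- expand.grid(cost = cost_grid, gamma = gamma0 * gamma_factors)
    set.seed(derive_seed(seed, 300 + k))
    folds <- integer(length(y))
    for (cls in levels(y)) {
      sel <- which(y == cls)
      folds[sel] <- sample(rep(seq_len(k_folds), length.out = length(sel)))
    }
    cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
      hits <- 0
      for (f in seq_len(k_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2L) next
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = grid$cost[g], gamma = grid$gamma[g],
                          scale = TRUE)
        hits <- hits + sum(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }
      hits / length(y)
    }, numeric(1))
    best <- which.max(cv_acc)
    fit <- e1071::svm(x, y, kernel = "radial", cost = grid$cost[best],
                      gamma = grid$gamma[best], scale = TRUE)
    models[[k]] <- list(led_id = k, fit = fit, grid = grid,
                        selected = grid[best, ], cv_score = cv_acc[best])
  }
  structure(models, class = "fvep_models")
}

#' Combine the four binary decisions into one LED
#'
#' Evaluates each LED's model on its own feature pair and returns the LED
#' with the largest signed margin (always a unique four-class decision;
#' exact ties break to the lowest LED id).
#'
#' @param models an `fvep_models` set.
#' @param features one `fvep_features` matrix.
#' @return list with `predicted_led` and the four `margins`.
#' @export
combine_decisions <- function(models, features) {
  if (!inherits(models, "fvep_models") || length(models) != 4L ||
      any(vapply(models, is.null, TRUE))) {
    stop("need four trained LED models")
  }
  margins <- vapply(1:4, function(k) {
    svm_margins(models[[k]]$fit, matrix(unclass(features)[k, ], 1,
                                        dimnames = list(NULL, colnames(features))))
  }, numeric(1))
  list(predicted_led = which.max(margins), margins = margins)
}
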