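#' Trough-indexed sliding covariance matrices
#'
#' Dynamic covariance estimation: windows advance one GFP trough at a time
#' and each window spans from trough i to trough i + window_troughs - 1,
#' so window length adapts to the local microstate rate rather than the
#' wall clock.
#'
#' @param seg an `mc_segment`.
#' @param troughs a `gfp_series` from [gfp()] (or an integer vector of
#'   trough sample indices).
#' @param window_troughs troughs per window.
#' @param regularization relative ridge (fraction of mean diagonal) added
#'   to every matrix; short 8-channel windows are near-singular without it.
#' @return list with `matrices` (list of `spd_matrix`), `times`
#'   (window-center times, s) and `times_end` (window-end trough times —
#'   where new data enters the window, used to timestamp detected
#'   changes).
#' @export
sliding_covariances <- function(seg, troughs, window_troughs = 35,
                                regularization = 1e-8) {
  idx <- if (inherits(troughs, "gfp_series")) troughs$trough_indices else troughs
  if (length(idx) < window_troughs) {
    stop("need at least ", window_troughs, " troughs, got ", length(idx))
  }
  n_win <- length(idx) - window_troughs + 1L
  mats <- vector("list", n_win)
  times <- numeric(n_win)
  times_end <- numeric(n_win)
  for (i in seq_len(n_win)) {
    a <- idx[i]
    b <- idx[i + window_troughs - 1L]
    sub <- mc_segment(seg$samples[, a:b, drop = FALSE], seg$rate,
                      seg$channel_labels, seg$t0 + (a - 1) / seg$rate)
    mats[[i]] <- covariance(sub, regularization, relative = TRUE)
    times[i] <- seg$t0 + ((a + b) / 2 - 1) / seg$rate
    times_end[i] <- seg$t0 + (b - 1) / seg$rate
  }
  list(matrices = mats, times = times, times_end = times_end)
}

#' Eigenvalue entropy of an SPD matrix
#'
#' Shannon entropy of the trace-normalized eigenvalues: low entropy means
#' the spatial variance is concentrated in few components (a synchronized
#' topography).
#'
#' @param m an SPD matrix.
#' @return scalar >= 0 (at most log C).
#' @export
eigen_entropy <- function(m) {
  m <- assert_spd(m)
  lam <- eigen(unclass(m), symmetric = TRUE, only.values = TRUE)$values
  p <- lam / sum(lam)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Entropy-selected reference covariance
#'
#' Element-wise arithmetic mean of the five candidates with the lowest
#' eigenvalue entropy — the most synchronized moments of the reference
#' epoch, which the sustained task state is compared against.
#'
#' @param candidates list of SPD matrices (>= `n_lowest`).
#' @param n_lowest how many low-entropy candidates to average.
#' @return An `spd_matrix`.
#' @export
reference_matrix <- function(candidates, n_lowest = 5) {
  if (length(candidates) < n_lowest) {
    stop("need at least ", n_lowest, " candidate matrices, got ",
         length(candidates))
  }
  ent <- vapply(candidates, eigen_entropy, numeric(1))
  pick <- order(ent)[seq_len(n_lowest)]
  avg <- Reduce(`+`, lapply(candidates[pick], unclass)) / n_lowest
  assert_spd(avg)
  structure(avg, class = c("spd_matrix", "matrix", "array"))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' d(a, b) = ||Log(a^{-1/2} b a^{-1/2})||_F = sqrt(sum_c log^2 lambda_c),
#' with lambda_c the eigenvalues of the whitened matrix (natural log).
#' A true metric on the SPD cone, invariant to joint congruence
#' transforms (re-referencing, channel mixing).
#'
#' @param a,b SPD matrices of equal dimension.
#' @return scalar >= 0.
#' @export
air_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b))) stop("dimension mismatch")
  assert_spd(a); assert_spd(b)
  ea <- eigen(a, symmetric = TRUE)
  w <- ea$vectors %*% (t(ea$vectors) / sqrt(ea$values))
  m <- w %*% b %*% w
  lam <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Dynamic Riemannian distance series
#'
#' AIR distance of every trough-indexed sliding covariance window of the
#' target segment to the reference matrix.
#'
#' @param seg target `mc_segment`.
#' @param ref reference SPD matrix (see [reference_matrix()]).
#' @param troughs a `gfp_series` (or trough index vector) for `seg`.
#' @param window_troughs troughs per window.
#' @param regularization passed to [sliding_covariances()].
#' @return list of class `distance_series`: `values`, `times` (window
#'   centers, s).
#' @export
distance_series <- function(seg, ref, troughs, window_troughs = 35,
                            regularization = 1e-8) {
  sc <- sliding_covariances(seg, troughs, window_troughs, regularization)
  d <- vapply(sc$matrices, function(m) air_distance(m, ref), numeric(1))
  structure(list(values = d, times = sc$times, times_end = sc$times_end),
            class = "distance_series")
}

#' Derivative-threshold task-onset detection
#'
#' A candidate onset is the earliest series point whose first difference
#' exceeds `k1` standard deviations of the first differences and whose
#' centered second difference exceeds `k2` standard deviations of the
#' second differences. The detected point is then consistency-checked: if
#' the absolute difference between the mean distance over the three
#' troughs after and the three before the index reaches `jump_floor`, the
#' shift is deemed unrelated to the stimulus response and the caller
#' should re-derive the onset from the pupil trace (`adjusted_by_plr`).
#' With no candidate the trial is excluded.
#'
#' @param series a `distance_series` (length >= 7).
#' @param k1,k2 thresholds in SDs of the first/second derivative.
#' @param jump_floor flanking-difference floor, distance units.
#' @return list of class `onset_decision`: `detected_index`,
#'   `detected_time` (the trough at which the new state entered the
#'   detected window), `adjusted_by_plr`, `excluded`, `thresholds`.
#' @export
detect_onset <- function(series, k1 = 3, k2 = 4, jump_floor = 0.1) {
  d <- series$values
  n <- length(d)
  if (n < 7) stop("distance series too short (", n, " < 7)")
  f1 <- diff(d)
  f2 <- diff(d, differences = 2)
  thr1 <- k1 * stats::sd(f1)
  thr2 <- k2 * stats::sd(f2)
  # candidate at series index j: first difference into j and the centered
  # second difference at j both significant
  cand <- which(abs(f1[seq_len(n - 2)]) > thr1 & abs(f2) > thr2) + 1L
  if (!length(cand)) {
    return(structure(list(detected_index = NA_integer_,
                          detected_time = NA_real_,
                          adjusted_by_plr = FALSE, excluded = TRUE,
                          thresholds = c(thr1, thr2)),
                     class = "onset_decision"))
  }
  j <- cand[1]
  pre <- d[max(1, j - 3):(j - 1)]
  post <- d[(j + 1):min(n, j + 3)]
  jump <- abs(mean(post) - mean(pre))
  t_det <- if (!is.null(series$times_end)) series$times_end[j] else series$times[j]
  structure(list(detected_index = j,
                 detected_time = t_det,
                 adjusted_by_plr = jump >= jump_floor, excluded = FALSE,
                 thresholds = c(thr1, thr2)),
            class = "onset_decision")
}

#' @export
print.onset_decision <- function(x, ...) {
  if (x$excluded) {
    cat("<onset_decision> excluded (no significant distance shift)\n")
  } else {
    cat(sprintf("<onset_decision> index %d (t = %.3f s)%s\n",
                x$detected_index, x$detected_time,
                if (x$adjusted_by_plr) ", to be adjusted by PLR" else ""))
  }
  invisible(x)
}

#' Pupil-based fallback onset estimate
#'
#' Time of the first sustained constriction whose downward velocity
#' exceeds `velocity_threshold` after the expected stimulus start,
#' corrected by the nominal reflex latency; `NA` if no such constriction
#' exists. The diameter is smoothed over 3 samples first and the crossing
#' must hold for `sustain_samples` consecutive samples, keeping the
#' 30 Hz sample-to-sample noise velocity below threshold.
#'
#' @param pupil a normalized `pupil_trial`.
#' @param expected_start earliest admissible stimulus time, s.
#' @param velocity_threshold constriction speed threshold, normalized
#'   units/s (positive number).
#' @param latency_correction assumed reflex latency subtracted from the
#'   crossing time, s.
#' @param sustain_samples consecutive supra-threshold samples required.
#' @return onset time in seconds, or `NA_real_`.
#' @export
plr_fallback_onset <- function(pupil, expected_start = 0,
                               velocity_threshold = 0.3,
                               latency_correction = 0.25,
                               sustain_samples = 2) {
  d <- (pupil$left + pupil$right) / 2
  d <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  v <- diff(d) * pupil$rate
  t_v <- pupil$t0 + seq_along(v) / pupil$rate
  fast <- !is.na(v) & v < -velocity_threshold & t_v >= expected_start
  r <- rle(as.vector(fast))
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= sustain_samples) {
      idx <- ends[i] - r$lengths[i] + 1L
      return(max(expected_start, t_v[idx] - latency_correction))
    }
  }
  NA_real_
}

#' Pre/post-onset epoch pair definitions
#'
#' The three reference/target epoch pairs used to probe the distance
#' dynamics around stimulus onset (seconds relative to onset):
#' Pair 1 (rest vs late rest), Pair 2 (rest vs task), Pair 3 (task vs
#' post-task rest).
#'
#' @return list of three lists with `ref_range` and `target_range`.
#' @export
default_epoch_pairs <- function() {
  list(list(ref_range = c(-4, -3), target_range = c(-3, 0)),
       list(ref_range = c(-3, 0), target_range = c(0, 5)),
       list(ref_range = c(0, 5), target_range = c(5, 8)))
}
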