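#' Re-reference a segment to one channel
#'
#' Subtracts the reference channel's series from every channel and drops
#' the reference channel from the output.
#'
#' @param seg an `mc_segment`.
#' @param ref_label label of the reference channel (e.g. `"Cz"`).
#' @return An `mc_segment` without the reference channel.
#' @export
rereference <- function(seg, ref_label) {
  if (!ref_label %in% seg$channel_labels) {
    stop("reference channel '", ref_label, "' not found; channels: ",
         paste(seg$channel_labels, collapse = ", "))
  }
  ref <- seg$samples[ref_label, ]
  keep <- setdiff(seg$channel_labels, ref_label)
  out <- sweep(seg$samples[keep, , drop = FALSE], 2, ref, "-")
  mc_segment(out, seg$rate, keep, seg$t0)
}

#' Zero-phase IIR band-pass filter
#'
#' Designs a Butterworth or elliptic band-pass and applies it forward and
#' backward (`signal::filtfilt`), so epoch latencies are not shifted by
#' group delay.
#'
#' @param seg an `mc_segment`.
#' @param low,high cutoff frequencies in Hz, `0 < low < high < rate/2`.
#' @param family `"butterworth"` or `"elliptic"`.
#' @param order filter order (applied twice by the forward-backward pass).
#' @param ripple_db passband ripple for the elliptic design, dB.
#' @param stop_db stopband attenuation for the elliptic design, dB.
#' @return The filtered `mc_segment`.
#' @export
bandpass <- function(seg, low, high, family = c("butterworth", "elliptic"),
                     order = 3, ripple_db = 1, stop_db = 40) {
  family <- match.arg(family)
  nyq <- seg$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("need 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  w <- c(low, high) / nyq
  flt <- if (family == "butterworth") {
    signal::butter(order, w, type = "pass")
  } else {
    signal::ellip(order, Rp = ripple_db, Rs = stop_db, W = w, type = "pass")
  }
  out <- t(apply(seg$samples, 1, function(x) signal::filtfilt(flt, x)))
  mc_segment(out, seg$rate, seg$channel_labels, seg$t0)
}

#' Global field power and its local troughs
#'
#' GFP is the root-mean-square deviation of the channel voltages from their
#' instantaneous mean, G(t) = sqrt( sum_i (V_i(t) - Vmean(t))^2 / C ). Its
#' local troughs mark boundaries of quasi-stable scalp topographies and are
#' used as the sample points of the dynamic covariance windows.
#'
#' Troughs are strict local minima over a 3-sample neighbourhood; a plateau
#' lower than both flanks is resolved to its first sample.
#'
#' @param seg an `mc_segment` with at least 2 channels.
#' @return An object of class `gfp_series`: list with `values` (length-N
#'   numeric), `trough_indices` (integer sample indices) and `rate`, `t0`.
#' @export
gfp <- function(seg) {
  if (nrow(seg$samples) < 2L) stop("GFP needs at least 2 channels")
  dev <- sweep(seg$samples, 2, colMeans(seg$samples), "-")
  g <- sqrt(colMeans(dev^2))
  n <- length(g)
  idx <- integer(0)
  if (n >= 3L) {
    i <- 2:(n - 1)
    idx <- i[g[i] < g[i - 1] & g[i] <= g[i + 1]]
  }
  structure(list(values = g, trough_indices = idx,
                 rate = seg$rate, t0 = seg$t0),
            class = "gfp_series")
}

#' Channel covariance of a segment
#'
#' Sigma = X X^T / (N - 1), uncentered, plus `regularization` on the
#' diagonal. Band-passed EEG is near zero-mean, so the uncentered product is
#' essentially the sample covariance; a `center` flag subtracts row means
#' first.
#'
#' @param seg an `mc_segment` with N >= 2 samples.
#' @param regularization ridge added to the diagonal (same units as the
#'   covariance); with `relative = TRUE` it is scaled by `trace/C`.
#' @param center subtract per-channel means before the product.
#' @param relative interpret `regularization` as a fraction of the mean
#'   diagonal element.
#' @return A symmetric C x C matrix of class `spd_matrix`.
#' @export
covariance <- function(seg, regularization = 0, center = FALSE,
                       relative = FALSE) {
  x <- seg$samples
  n <- ncol(x)
  if (n < 2L) stop("covariance needs N >= 2 samples")
  if (center) x <- x - rowMeans(x)
  s <- tcrossprod(x) / (n - 1)
  s <- (s + t(s)) / 2
  if (regularization > 0) {
    ridge <- if (relative) regularization * mean(diag(s)) else regularization
    s <- s + diag(ridge, nrow(s))
  }
  structure(s, class = c("spd_matrix", "matrix", "array"))
}

#' Assert the symmetric-positive-definite contract
#'
#' @param m a square numeric matrix.
#' @param tol symmetry tolerance.
#' @return `m` (invisibly classed `spd_matrix`) or an error.
#' @export
assert_spd <- function(m, tol = 1e-10) {
  m <- unclass(m)
  if (nrow(m) != ncol(m)) stop("not square")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) stop("not symmetric")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("not positive definite (min eigenvalue ", min(ev), ")")
  invisible(structure(m, class = c("spd_matrix", "matrix", "array")))
}

#' Cut transition-locked epochs out of a segment
#'
#' Half-open window `[pre, post)` on the sample grid: every epoch has
#' exactly `round((post - pre)/1000 * rate)` samples. Events whose window
#' extends beyond the segment are dropped and counted.
#'
#' @param seg an `mc_segment`.
#' @param events numeric vector of event times (seconds, trial clock).
#' @param window_ms `c(pre, post)` window around each event in ms
#'   (pre typically negative, e.g. `c(-100, 350)`).
#' @return list with `epochs` (list of `mc_segment`, each `t0` = event +
#'   pre) and `n_dropped`. Warns when every event is out of range.
#' @export
epoch <- function(seg, events, window_ms = c(-100, 350)) {
  if (diff(window_ms) <= 0) stop("epoch window must have positive span")
  n_samp <- round(diff(window_ms) / 1000 * seg$rate)
  out <- list()
  dropped <- 0L
  for (ev in events) {
    i0 <- round((ev + window_ms[1] / 1000 - seg$t0) * seg$rate) + 1
    i1 <- i0 + n_samp - 1
    if (i0 < 1 || i1 > ncol(seg$samples)) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <-
      mc_segment(seg$samples[, i0:i1, drop = FALSE], seg$rate,
                 seg$channel_labels, ev + window_ms[1] / 1000)
  }
  if (length(events) > 0 && length(out) == 0L) {
    warning("all ", length(events), " events fell outside the segment")
  }
  list(epochs = out, n_dropped = dropped)
}
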