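#' Analytic generalized Morse wavelet transform
#'
#' Continuous wavelet transform with the generalized Morse wavelet
#' (shape gamma, time-bandwidth product P^2 = beta * gamma), evaluated in
#' the frequency domain: psi_hat(w) = 2 (w/w_p)^beta exp((beta/gamma)(1 -
#' (w/w_p)^gamma)) for w > 0 (peak value 2 at the peak angular frequency
#' w_p = (beta/gamma)^(1/gamma)), zero for w <= 0, so the transform is
#' analytic and insensitive to a constant offset.
#'
#' @param x real signal vector.
#' @param rate sampling rate, Hz.
#' @param freqs center frequencies, Hz.
#' @param gamma Morse shape parameter (3 = the symmetric "airy" family).
#' @param time_bandwidth P^2 product; beta = P^2 / gamma.
#' @return complex matrix, `length(freqs)` x `length(x)`; take `Mod(.)^2`
#'   for wavelet power.
#' @export
morse_cwt <- function(x, rate, freqs, gamma = 3, time_bandwidth = 60) {
  beta <- time_bandwidth / gamma
  n <- length(x)
  if (any(freqs >= rate / 2)) {
    stop("requested frequencies reach the Nyquist rate (", rate / 2, " Hz)")
  }
  wp <- (beta / gamma)^(1 / gamma)
  xf <- stats::fft(x)
  # angular frequencies of the DFT bins (positive half only: analytic)
  k <- seq_len(n) - 1
  w_bin <- 2 * pi * ifelse(k <= n / 2, k, k - n) * rate / n
  out <- matrix(0 + 0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- wp / (2 * pi * freqs[i])
    sw <- s * w_bin
    psi <- numeric(n)
    pos <- sw > 0
    psi[pos] <- 2 * exp(beta * log(sw[pos] / wp) +
                          (beta / gamma) * (1 - (sw[pos] / wp)^gamma))
    out[i, ] <- stats::fft(xf * psi, inverse = TRUE) / n
  }
  out
}

#' Spectro-temporal pupil feature tensor
#'
#' Morse-wavelet power of each eye's normalized diameter series on
#' `rows_per_eye` log-spaced frequencies inside `freq_range`, the two eyes
#' stacked along the frequency axis (left block above right block), and
#' the time axis symmetrically edge-padded to exactly `n_time` columns.
#' With the defaults this reproduces the 122 x 139 input contract of the
#' pattern classifier.
#'
#' @param trial a normalized `pupil_trial` (see [normalize_pupil()]).
#' @param gamma,time_bandwidth Morse parameters.
#' @param freq_range `c(low, high)` Hz; the default upper edge 1.75 Hz
#'   covers the shortest flicker cycle (LED 2, 350/350 ms).
#' @param rows_per_eye frequency rows per eye.
#' @param n_time output time points.
#' @return numeric matrix `2*rows_per_eye` x `n_time` of class
#'   `plr_tensor`, with attributes `freqs` and `target_led`.
#' @export
cwt_features <- function(trial, gamma = 3, time_bandwidth = 60,
                         freq_range = c(0.5, 1.75), rows_per_eye = 61,
                         n_time = 139) {
  if (is.null(trial$normalized)) {
    stop("cwt_features expects a normalized trial; call normalize_pupil() first")
  }
  if (freq_range[2] >= trial$rate / 2) {
    stop("freq_range upper edge must be below Nyquist (", trial$rate / 2, " Hz)")
  }
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = rows_per_eye))
  pw <- function(x) Mod(morse_cwt(x - mean(x), trial$rate, freqs,
                                  gamma, time_bandwidth))^2
  feat <- rbind(pw(trial$left), pw(trial$right))
  tcur <- ncol(feat)
  if (tcur > n_time) {
    feat <- feat[, seq_len(n_time), drop = FALSE]
  } else if (tcur < n_time) {
    extra <- n_time - tcur
    padl <- extra %/% 2
    padr <- extra - padl
    feat <- cbind(feat[, rep(1, padl), drop = FALSE], feat,
                  feat[, rep(tcur, padr), drop = FALSE])
  }
  structure(feat, class = c("plr_tensor", "matrix", "array"),
            freqs = freqs, target_led = trial$target_led)
}
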