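#' Sin/cos reference bank for one stimulation frequency
#'
#' @param freq fundamental frequency, Hz.
#' @param n_harmonics number of harmonics (fundamental counts as the
#'   first).
#' @param rate sampling rate, Hz.
#' @param n_samples samples to generate.
#' @return An `mc_segment` with `2 * n_harmonics` rows: sin/cos pairs at
#'   freq, 2*freq, ...
#' @export
reference_bank <- function(freq, n_harmonics, rate, n_samples) {
  if (freq * n_harmonics >= rate / 2) {
    stop("freq x n_harmonics (", freq * n_harmonics,
         " Hz) reaches Nyquist (", rate / 2, " Hz)")
  }
  t <- (seq_len(n_samples) - 1) / rate
  rows <- do.call(rbind, lapply(seq_len(n_harmonics), function(h) {
    rbind(sin(2 * pi * h * freq * t), cos(2 * pi * h * freq * t))
  }))
  labels <- as.vector(t(outer(seq_len(n_harmonics), c("sin", "cos"),
                              function(h, f) paste0(f, h))))
  mc_segment(rows, rate, labels, 0)
}

inv_sqrt_sym <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-12)
  e$vectors %*% (t(e$vectors) / sqrt(v))
}

#' Multivariate synchronization index
#'
#' Entropy-based synchronization between a multichannel signal and a
#' sinusoidal reference bank: the joint correlation matrix of the stacked
#' rows is whitened block-wise (so the index is amplitude-invariant and
#' symmetric in its arguments), and S = 1 + sum(l' log l') / log M from its
#' trace-normalized eigenvalues l', M the total dimension. S is 0 for
#' independent signals and grows toward its attainable maximum as the
#' signal synchronizes with the reference; the maximum is 1 in the
#' one-dimensional case.
#'
#' @param eeg an `mc_segment` (occipital channels).
#' @param ref an `mc_segment` with the same sample count (see
#'   [reference_bank()]).
#' @return scalar index in [0, 1].
#' @export
synchronization_index <- function(eeg, ref) {
  x <- eeg$samples
  y <- ref$samples
  if (ncol(x) != ncol(y)) stop("eeg and reference sample counts differ")
  for (nm in rownames(x)) {
    if (stats::sd(x[nm, ]) == 0) stop("zero-variance channel: ", nm)
  }
  z <- rbind(x, y)
  r <- stats::cor(t(z))
  cx <- seq_len(nrow(x))
  cy <- nrow(x) + seq_len(nrow(y))
  u1 <- inv_sqrt_sym(r[cx, cx, drop = FALSE])
  u2 <- inv_sqrt_sym(r[cy, cy, drop = FALSE])
  rt <- r
  rt[cx, cx] <- diag(length(cx))
  rt[cy, cy] <- diag(length(cy))
  rt[cx, cy] <- u1 %*% r[cx, cy, drop = FALSE] %*% u2
  rt[cy, cx] <- t(rt[cx, cy])
  m <- nrow(rt)
  lam <- eigen((rt + t(rt)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  lp <- lam / sum(lam)
  h <- -sum(ifelse(lp > 0, lp * log(lp), 0))
  max(0, min(1, 1 - h / log(m)))
}

#' Four-class SSVEP decision
#'
#' Computes the synchronization index against each frequency of the bank
#' on the analysis window and picks the argmax (ties break to the lowest
#' LED id).
#'
#' @param eeg an `mc_segment` restricted to the analysis window.
#' @param bank frequencies, Hz, indexed by LED id.
#' @param n_harmonics harmonics per reference.
#' @param channels channels to use; default the occipital triplet.
#' @return list of class `ssvep_decision`: `per_frequency_index` (named by
#'   frequency) and `predicted_led`.
#' @export
classify_ssvep <- function(eeg, bank = c(6.6, 7.5, 8.57, 10),
                           n_harmonics = 2,
                           channels = c("O1", "Oz", "O2")) {
  seg <- select_channels(eeg, channels)
  idx <- vapply(bank, function(f) {
    synchronization_index(seg, reference_bank(f, n_harmonics, seg$rate,
                                              ncol(seg$samples)))
  }, numeric(1))
  names(idx) <- bank
  structure(list(per_frequency_index = idx,
                 predicted_led = unname(which.max(idx))),
            class = "ssvep_decision")
}

#' @export
print.ssvep_decision <- function(x, ...) {
  cat("<ssvep_decision> predicted LED", x$predicted_led, "\n")
  print(round(x$per_frequency_index, 4))
  invisible(x)
}
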