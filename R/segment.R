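#' Multichannel signal segment
#'
#' Container for a windowed multichannel time series (EEG, EMG, reference
#' sinusoid banks): a C x N numeric matrix with one row per channel, a
#' sampling rate and the time of the first sample relative to the trial
#' clock.
#'
#' @param samples numeric matrix, channels x samples (microvolts for EEG).
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector of unique channel names; defaults
#'   to the rownames of `samples`.
#' @param t0 time of the first sample in seconds relative to trial start.
#' @return An object of class `mc_segment`.
#' @export
mc_segment <- function(samples, rate, channel_labels = rownames(samples), t0 = 0) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (nrow(samples) < 1L || ncol(samples) < 2L) {
    stop("mc_segment needs at least 1 channel and 2 samples")
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match channel count (", nrow(samples), ")")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique: ",
         paste(channel_labels[duplicated(channel_labels)], collapse = ", "))
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = channel_labels, t0 = t0),
            class = "mc_segment")
}

#' @export
print.mc_segment <- function(x, ...) {
  cat(sprintf("<mc_segment> %d channels x %d samples @ %g Hz, t0 = %.3f s\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$t0))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.mc_segment <- function(x, ...) x$samples

#' Sample times of a segment
#'
#' @param seg an `mc_segment`.
#' @return numeric vector of sample times in seconds (trial clock).
#' @export
segment_times <- function(seg) {
  seg$t0 + (seq_len(ncol(seg$samples)) - 1L) / seg$rate
}

#' Restrict a segment to a subset of channels
#'
#' @param seg an `mc_segment`.
#' @param channels character vector of channel labels to keep, in order.
#' @return An `mc_segment` with only the requested channels.
#' @export
select_channels <- function(seg, channels) {
  missing <- setdiff(channels, seg$channel_labels)
  if (length(missing)) {
    stop("channels not present: ", paste(missing, collapse = ", "),
         "; available: ", paste(seg$channel_labels, collapse = ", "))
  }
  mc_segment(seg$samples[channels, , drop = FALSE], seg$rate, channels, seg$t0)
}

#' Cut a segment to a time window
#'
#' Half-open window `[from, to)` on the sample grid of the trial clock.
#'
#' @param seg an `mc_segment`.
#' @param from,to window bounds in seconds (trial clock).
#' @return An `mc_segment` covering the window.
#' @export
crop_segment <- function(seg, from, to) {
  if (to <= from) stop("empty window: to <= from")
  i0 <- round((from - seg$t0) * seg$rate) + 1
  i1 <- round((to - seg$t0) * seg$rate)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(ncol(seg$samples), as.integer(i1))
  if (i1 - i0 + 1L < 2L) stop("window [", from, ", ", to, ") falls outside segment")
  mc_segment(seg$samples[, i0:i1, drop = FALSE], seg$rate, seg$channel_labels,
             seg$t0 + (i0 - 1L) / seg$rate)
}
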