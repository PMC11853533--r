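#' Write a multichannel segment as delimited text
#'
#' Tab-separated, one column per channel, with `# rate=` and `# t0=`
#' header comment lines followed by a column-label header row.
#'
#' @param seg an `mc_segment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(seg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate=%.10g", seg$rate),
               sprintf("# t0=%.10g", seg$t0)), con)
  utils::write.table(t(seg$samples), con, sep = "\t", row.names = FALSE,
                     col.names = seg$channel_labels, quote = FALSE)
  invisible(path)
}

#' Read a delimited-text multichannel segment
#'
#' @param path file written by [write_eeg()] (or any delimited file with
#'   the same header convention).
#' @return An `mc_segment`.
#' @export
read_eeg <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- grep("^# *[a-z0-9_]+=", hdr, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# *", key, "="), meta, value = TRUE)
    if (!length(ln)) stop("malformed header: missing '# ", key, "=' line in ", path)
    as.numeric(sub(paste0("^# *", key, "="), "", ln[1]))
  }
  rate <- get("rate")
  t0 <- get("t0")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  if (ncol(tab) < 1 || nrow(tab) < 2) stop("no sample data in ", path)
  mc_segment(t(as.matrix(tab)), rate, colnames(tab), t0)
}

#' Write a pupil trial as an eye-tracker-style CSV
#'
#' Long format with columns `pupil_timestamp` (s), `eye_id` (0 = right,
#' 1 = left), `confidence`, `diameter_3d` (mm).
#'
#' @param trial a `pupil_trial`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pupil <- function(trial, path) {
  t <- trial$t0 + (seq_along(trial$left) - 1) / trial$rate
  df <- rbind(
    data.frame(pupil_timestamp = t, eye_id = 1L,
               confidence = trial$conf_left, diameter_3d = trial$left),
    data.frame(pupil_timestamp = t, eye_id = 0L,
               confidence = trial$conf_right, diameter_3d = trial$right))
  utils::write.csv(df[order(df$pupil_timestamp, df$eye_id), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an eye-tracker-style pupil CSV
#'
#' Rows are sorted by timestamp and split by `eye_id` (0 = right,
#' 1 = left); both eyes are aligned onto the common grid implied by the
#' timestamps. A file with only one eye is read in monocular mode (the
#' present eye duplicated) with a warning.
#'
#' @param path CSV with columns `pupil_timestamp`, `eye_id`,
#'   `confidence`, `diameter_3d`.
#' @param rate sampling rate of the output grid, Hz; inferred from the
#'   median timestamp step when `NULL`.
#' @return A `pupil_trial`.
#' @export
read_pupil <- function(path, rate = NULL) {
  df <- utils::read.csv(path)
  need <- c("pupil_timestamp", "eye_id", "confidence", "diameter_3d")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$pupil_timestamp), ]
  eyes <- lapply(c(left = 1L, right = 0L), function(e) df[df$eye_id == e, ])
  if (nrow(eyes$left) == 0 || nrow(eyes$right) == 0) {
    warning("only one eye present; monocular mode")
    have <- if (nrow(eyes$left) > 0) eyes$left else eyes$right
    eyes$left <- have
    eyes$right <- have
  }
  if (is.null(rate)) {
    rate <- 1 / stats::median(diff(eyes$left$pupil_timestamp))
  }
  t0 <- min(df$pupil_timestamp)
  t_end <- max(df$pupil_timestamp)
  grid <- seq(t0, t_end, by = 1 / rate)
  on_grid <- function(e, col) {
    stats::approx(e$pupil_timestamp, e[[col]], xout = grid, rule = 2)$y
  }
  pupil_trial(on_grid(eyes$left, "diameter_3d"),
              on_grid(eyes$right, "diameter_3d"),
              on_grid(eyes$left, "confidence"),
              on_grid(eyes$right, "confidence"),
              rate = rate, t0 = t0)
}

#' Write a schedule event table
#'
#' @param schedule a `stim_schedule`.
#' @param path TSV output (`time_s`, `led_id`, `transition`).
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  utils::write.table(schedule_events(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Schedule config round-trip (YAML)
#'
#' @param schedule a `stim_schedule`.
#' @param path YAML file.
#' @return `path`, invisibly.
#' @export
write_schedule_yaml <- function(schedule, path) {
  cfg <- lapply(schedule$patterns, function(p) {
    list(led_id = p$led_id, mode = p$mode,
         frequency_hz = p$frequency, delay_ms = p$start_delay_ms,
         on_ms = p$on_ms, off_ms = p$off_ms,
         full_off_ms = p$full_off_ms, trial_ms = p$trial_ms)
  })
  yaml::write_yaml(list(leds = cfg), path)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  stim_schedule(lapply(cfg$leds, function(p) {
    led_pattern(p$led_id, p$mode, frequency = p$frequency_hz,
                start_delay_ms = p$delay_ms, on_ms = p$on_ms,
                off_ms = p$off_ms, full_off_ms = p$full_off_ms,
                trial_ms = p$trial_ms)
  }))
}

#' Write a dataset manifest
#'
#' JSON listing per-trial file paths and ground truth, so on-disk
#' datasets are explicit and versionable.
#'
#' @param entries data.frame with at least `subject`, `trial`,
#'   `target_led` and any path columns.
#' @param path JSON output.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  jsonlite::write_json(entries, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path)
}
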