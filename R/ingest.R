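# Raw-recording container plus the raw CSV dialect:
#   hour,minute,second,millisecond,day,month,year,ax,ay,az
# one row per 100 Hz sample, acceleration in m/s^2, written to 6 decimals.

RAW_COLUMNS <- c("hour", "minute", "second", "millisecond",
                 "day", "month", "year", "ax", "ay", "az")

#' Construct a raw recording
#'
#' @param participant_id,session_id identity strings.
#' @param sampling_rate Hz.
#' @param timestamps_ms milliseconds since the first sample (monotone).
#' @param accel n x 3 numeric matrix (columns x, y, z), m/s^2.
#' @param start_time POSIXct wall-clock time of the first sample.
#' @param segment_starts 1-based indices where a new contiguous segment
#'   begins (timestamp gaps split segments; data are never interpolated).
#' @return a `raw_recording` object.
#' @export
raw_recording <- function(participant_id, session_id, sampling_rate,
                          timestamps_ms, accel,
                          start_time = as.POSIXct("2024-01-01", tz = "UTC"),
                          segment_starts = 1L) {
  accel <- as.matrix(accel)
  stopifnot(ncol(accel) == 3, nrow(accel) >= 1,
            length(timestamps_ms) == nrow(accel))
  if (any(!is.finite(accel))) stop("accel contains non-finite values")
  if (any(diff(timestamps_ms) <= 0))
    stop("timestamps must be strictly increasing (first violation at row ",
         which(diff(timestamps_ms) <= 0)[1] + 1L, ")")
  colnames(accel) <- c("ax", "ay", "az")
  structure(list(participant_id = participant_id, session_id = session_id,
                 sampling_rate = sampling_rate,
                 timestamps_ms = as.numeric(timestamps_ms),
                 accel = accel, start_time = start_time,
                 segment_starts = as.integer(segment_starts)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s/%s: %d samples @ %g Hz (%.1f s), %d segment(s)\n",
              x$participant_id, x$session_id, nrow(x$accel), x$sampling_rate,
              nrow(x$accel) / x$sampling_rate, length(x$segment_starts)))
  invisible(x)
}

#' Write a recording in the raw smartwatch CSV dialect
#'
#' @param rec a [raw_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  wall <- rec$start_time + rec$timestamps_ms / 1000
  lt <- as.POSIXlt(wall, tz = "UTC")
  ms <- round((rec$timestamps_ms %% 1000))
  df <- data.table::data.table(
    hour = lt$hour, minute = lt$min, second = floor(lt$sec),
    millisecond = as.integer(round(rec$timestamps_ms -
                                   floor(rec$timestamps_ms / 1000) * 1000)),
    day = lt$mday, month = lt$mon + 1L, year = lt$year + 1900L,
    ax = sprintf("%.6f", rec$accel[, 1]),
    ay = sprintf("%.6f", rec$accel[, 2]),
    az = sprintf("%.6f", rec$accel[, 3]))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a raw smartwatch CSV
#'
#' Parses the raw dialect, converts wall-clock fields to milliseconds since
#' the first row, and validates integrity. Timestamp gaps larger than 3
#' sample periods split the recording into segments (recorded in
#' `segment_starts`) rather than interpolating. Gyroscope columns
#' (`gx,gy,gz`), if present, are parsed and ignored.
#'
#' @param path CSV file in the raw dialect.
#' @param sampling_rate nominal rate, Hz.
#' @param participant_id,session_id identity (defaults parsed from the
#'   file name when it matches `P.._S..`).
#' @return a [raw_recording()].
#' @export
read_raw_csv <- function(path, sampling_rate = 100,
                         participant_id = NULL, session_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  if (nrow(dt) == 0) stop("empty raw CSV: ", path)
  missing_cols <- setdiff(RAW_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("raw CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(dt), c(RAW_COLUMNS, "gx", "gy", "gz"))
  if (length(extra))
    stop("raw CSV has unexpected column(s): ", paste(extra, collapse = ", "))
  wall <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                             dt$year, dt$month, dt$day,
                             dt$hour, dt$minute, dt$second),
                     tz = "UTC") + dt$millisecond / 1000
  ts <- as.numeric(difftime(wall, wall[1], units = "secs")) * 1000
  ts <- round(ts)  # the dialect stores integer milliseconds
  bad <- which(diff(ts) <= 0)
  if (length(bad))
    stop("non-monotone timestamps in ", path, " (first offending row ",
         bad[1] + 1L, ")")
  period_ms <- 1000 / sampling_rate
  med_gap <- stats::median(diff(ts))
  if (nrow(dt) > 1 && abs(med_gap - period_ms) > 0.1 * period_ms)
    stop(sprintf("median inter-sample gap %.2f ms inconsistent with %g Hz",
                 med_gap, sampling_rate))
  seg <- c(1L, which(diff(ts) > 3 * period_ms) + 1L)
  stem <- sub("\\.csv$", "", basename(path))
  ids <- regmatches(stem, regexec("^(P[0-9]+)_(S[0-9]+)", stem))[[1]]
  raw_recording(
    participant_id = participant_id %||% (if (length(ids)) ids[2] else stem),
    session_id = session_id %||% (if (length(ids)) ids[3] else "S01"),
    sampling_rate = sampling_rate,
    timestamps_ms = ts,
    accel = as.matrix(dt[, c("ax", "ay", "az")]),
    start_time = wall[1],
    segment_starts = seg)
}

#' Read a ground-truth / annotation sidecar CSV
#'
#' @param path sidecar CSV (`kind,label,wrist,phase_mode,start_sample,end_sample`).
#' @return a data.frame sorted by `start_sample`.
#' @export
read_sidecar_csv <- function(path) {
  sc <- as.data.frame(data.table::fread(path, showProgress = FALSE,
                                        colClasses = list(character = c("kind", "label", "wrist", "phase_mode"))))
  need <- c("kind", "label", "wrist", "phase_mode", "start_sample", "end_sample")
  miss <- setdiff(need, names(sc))
  if (length(miss)) stop("sidecar missing column(s): ", paste(miss, collapse = ", "))
  sc[order(sc$start_sample), need]
}

#' Detect vigorous-shake markers in a recording
#'
#' High-pass filters each acceleration axis (4th-order Butterworth,
#' zero-phase) to strip gravity and slow movement, takes a moving RMS of
#' the filtered vector magnitude, and returns the maximal intervals where
#' the RMS exceeds `threshold` for at least `min_duration`. Defaults are
#' matched to the generator's declared shake morphology (4 Hz, 1 s,
#' 15 m/s^2 burst) but exposed for re-tuning on other data.
#'
#' @param rec a [raw_recording()].
#' @param highpass_cutoff high-pass corner frequency, Hz.
#' @param rms_window moving-RMS window, seconds.
#' @param threshold RMS threshold, m/s^2.
#' @param min_duration minimum marker length, seconds.
#' @return data.frame with 0-based half-open `start_sample`, `end_sample`.
#' @export
detect_shake_markers <- function(rec, highpass_cutoff = 3, rms_window = 0.25,
                                 threshold = 5, min_duration = 0.4) {
  stopifnot(inherits(rec, "raw_recording"))
  if (highpass_cutoff <= 0 || rms_window <= 0 || threshold <= 0 ||
      min_duration <= 0)
    stop("shake-detector parameters must be positive")
  rate <- rec$sampling_rate
  n <- nrow(rec$accel)
  w <- max(3L, round(rms_window * rate))
  if (n < w)
    stop(sprintf("recording too short (%d samples) for a %.2f s RMS window",
                 n, rms_window))
  bf <- signal::butter(4, highpass_cutoff / (rate / 2), type = "high")
  hp <- apply(rec$accel, 2, function(ch) signal::filtfilt(bf, ch))
  # centered moving RMS of the filtered vector magnitude
  ms <- stats::filter(rowSums(hp^2), rep(1 / w, w), sides = 2)
  ms[is.na(ms)] <- 0
  rms <- sqrt(pmax(as.numeric(ms), 0))
  above <- rms > threshold
  if (!any(above)) return(empty_intervals())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= round(min_duration * rate))
  if (!any(keep)) return(empty_intervals())
  data.frame(start_sample = starts[keep] - 1L, end_sample = ends[keep])
}

empty_intervals <- function()
  data.frame(start_sample = integer(0), end_sample = integer(0))

#' Segment labeled gesture bouts from shake markers
#'
#' Consecutive marker pairs (1st-2nd, 3rd-4th, ...) delimit candidate
#' gestures: the candidate interval runs from the end of the leading shake
#' to the start of the trailing shake. Each candidate must be covered by an
#' annotation (label + wrist, or `"discard"`); unlabeled or discarded
#' candidates are dropped and counted, mirroring a labeling workflow where
#' low-confidence gestures are excluded.
#'
#' @param rec a [raw_recording()].
#' @param markers data.frame of shake intervals (sorted, non-overlapping).
#' @param annotations data.frame with one row per candidate (in order):
#'   columns `label` (class or `"discard"`) and optionally `wrist`,
#'   `phase_mode`.
#' @return list with `bouts` (a bout data.frame: recording_ref, label,
#'   wrist, phase_mode, start_sample, end_sample) and `n_discarded`.
#' @export
segment_bouts <- function(rec, markers, annotations) {
  stopifnot(inherits(rec, "raw_recording"))
  m <- markers[order(markers$start_sample), , drop = FALSE]
  if (nrow(m) >= 2 && any(m$start_sample[-1] < m$end_sample[-nrow(m)]))
    stop("overlapping shake markers")
  n_cand <- nrow(m) %/% 2L
  if (nrow(annotations) < n_cand)
    stop(sprintf("%d candidates but only %d annotations", n_cand,
                 nrow(annotations)))
  keep <- list(); dropped <- 0L
  for (k in seq_len(n_cand)) {
    lead <- m[2L * k - 1L, ]; trail <- m[2L * k, ]
    ann <- annotations[k, , drop = FALSE]
    if (identical(ann$label, "discard") || is.na(ann$label)) {
      dropped <- dropped + 1L
      next
    }
    keep[[length(keep) + 1L]] <- data.frame(
      recording_ref = paste0(rec$participant_id, "_", rec$session_id),
      label = ann$label,
      wrist = if ("wrist" %in% names(ann)) ann$wrist else "unknown",
      phase_mode = if ("phase_mode" %in% names(ann)) ann$phase_mode else "unknown",
      start_sample = lead$end_sample,
      end_sample = trail$start_sample)
  }
  bouts <- if (length(keep)) do.call(rbind, keep) else
    data.frame(recording_ref = character(0), label = character(0),
               wrist = character(0), phase_mode = character(0),
               start_sample = integer(0), end_sample = integer(0))
  if (nrow(bouts) && any(bouts$end_sample <= bouts$start_sample))
    stop("degenerate bout interval (trailing shake precedes leading shake end)")
  list(bouts = bouts, n_discarded = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
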