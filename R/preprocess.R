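# Fixed-length windowing: every bout becomes one 4 s x 3 channel window
# centered on the bout midpoint, taking real surrounding recording context
# where available and zero-padding (post-standardization zeros = channel
# means) only at recording edges. Bouts longer than the window are
# center-cropped by default to maximize data retention.

#' Fraction of bouts retained by a window length
#'
#' @param durations bout durations in seconds (non-empty, positive).
#' @param window_len window length in seconds.
#' @return fraction of durations `<= window_len`, in \[0,1\].
#' @export
compute_retention <- function(durations, window_len) {
  if (length(durations) == 0) stop("durations must be non-empty")
  if (any(durations <= 0)) stop("durations must be positive")
  mean(durations <= window_len)
}

#' Extract one fixed-length window around a bout
#'
#' @param rec a [raw_recording()].
#' @param bout one-row bout data.frame (0-based half-open
#'   `start_sample`/`end_sample`).
#' @param window_len window length, seconds (default 4).
#' @return list: `data` (3 x L matrix, L = `round(window_len * rate)`),
#'   `padded` flag, `pad_left`/`pad_right` sample counts.
#' @export
extract_window <- function(rec, bout, window_len = 4) {
  if (window_len <= 0) stop("window_len must be positive")
  rate <- rec$sampling_rate
  L <- round(window_len * rate)
  n <- nrow(rec$accel)
  mid <- (bout$start_sample + bout$end_sample) / 2
  w0 <- round(mid - L / 2)            # 0-based inclusive start
  pad_left <- max(0L, -w0)
  pad_right <- max(0L, (w0 + L) - n)
  i0 <- max(0L, w0); i1 <- min(n, w0 + L)
  data <- matrix(0, 3, L)
  if (i1 > i0)
    data[, (pad_left + 1L):(pad_left + (i1 - i0))] <- t(rec$accel[(i0 + 1L):i1, , drop = FALSE])
  rownames(data) <- c("ax", "ay", "az")
  list(data = data, padded = (pad_left + pad_right) > 0L,
       pad_left = pad_left, pad_right = pad_right)
}

#' Build a window set from bouts of one or more recordings
#'
#' @param recordings named list of [raw_recording()]s, keyed by
#'   `recording_ref` (e.g. `P01_S01`).
#' @param bouts bout data.frame with `recording_ref`, `label`, and sample
#'   bounds; a `bout_ref` column is added if absent.
#' @param window_len seconds.
#' @return a `window_set`: `data` array (3 x L x n), `labels`,
#'   `provenance` data.frame (bout_ref, recording_ref, participant_id,
#'   label, wrist, padded).
#' @export
extract_windows <- function(recordings, bouts, window_len = 4) {
  if (!nrow(bouts)) stop("no bouts to window")
  if (!"bout_ref" %in% names(bouts))
    bouts$bout_ref <- sprintf("%s_b%03d", bouts$recording_ref,
                              stats::ave(seq_len(nrow(bouts)), bouts$recording_ref,
                                         FUN = seq_along))
  first <- recordings[[bouts$recording_ref[1]]]
  L <- round(window_len * first$sampling_rate)
  dat <- array(0, c(3, L, nrow(bouts)))
  padded <- logical(nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    rec <- recordings[[bouts$recording_ref[i]]]
    if (is.null(rec)) stop("no recording for ref ", bouts$recording_ref[i])
    w <- extract_window(rec, bouts[i, ], window_len)
    dat[, , i] <- w$data
    padded[i] <- w$padded
  }
  prov <- data.frame(
    bout_ref = bouts$bout_ref,
    recording_ref = bouts$recording_ref,
    participant_id = sub("_S[0-9]+$", "", bouts$recording_ref),
    label = bouts$label,
    wrist = if ("wrist" %in% names(bouts)) bouts$wrist else "unknown",
    padded = padded)
  structure(list(data = dat, labels = bouts$label, provenance = prov,
                 window_len = window_len, sampling_rate = first$sampling_rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of 3 x %d (%g s @ %g Hz); classes: %s\n",
              dim(x$data)[3], dim(x$data)[2], x$window_len, x$sampling_rate,
              paste(names(table(x$labels)), table(x$labels), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

subset_windows <- function(ws, idx) {
  structure(list(data = ws$data[, , idx, drop = FALSE],
                 labels = ws$labels[idx],
                 provenance = ws$provenance[idx, , drop = FALSE],
                 window_len = ws$window_len, sampling_rate = ws$sampling_rate),
            class = "window_set")
}

#' Fit a per-channel standardizer on training windows
#'
#' Global per-channel z-scoring with statistics computed on the training
#' split only; applying the fitted stats elsewhere never refits, which is
#' the leakage-safety contract.
#'
#' @param train_ws a `window_set` restricted to training windows.
#' @param fitted_on split name recorded on the stats (must be "train" for
#'   pipeline use).
#' @return `standardizer` with per-channel `mean` and `sd`.
#' @export
fit_standardizer <- function(train_ws, fitted_on = "train") {
  if (dim(train_ws$data)[3] == 0) stop("cannot fit standardizer on empty set")
  m <- apply(train_ws$data, 1, mean)
  s <- apply(train_ws$data, 1, stats::sd)
  if (any(s <= 0))
    stop("degenerate (zero-variance) channel: ",
         paste(c("x", "y", "z")[s <= 0], collapse = ", "))
  structure(list(mean = m, sd = s, fitted_on = fitted_on),
            class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param stats a `standardizer`.
#' @param ws a `window_set`.
#' @param invert if `TRUE`, undo the standardization.
#' @return the transformed `window_set`.
#' @export
apply_standardizer <- function(stats, ws, invert = FALSE) {
  stopifnot(inherits(stats, "standardizer"))
  out <- ws
  for (c in 1:3) {
    if (invert) out$data[c, , ] <- ws$data[c, , ] * stats$sd[c] + stats$mean[c]
    else out$data[c, , ] <- (ws$data[c, , ] - stats$mean[c]) / stats$sd[c]
  }
  out
}
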