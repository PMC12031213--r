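# Session assembly: a session interleaves 20 medication bouts (each
# bracketed by wrist shakes, as the labeling protocol requires) with
# daily-living bouts and quiet rest gaps. Ground truth (bout boundaries,
# classes, wrists, shake markers) is emitted as a sidecar table.

#' Simulate one recording session
#'
#' Produces exactly `gestures_per_session_per_class` bouts per medication
#' class with the configured left/right wrist split, every medication bout
#' preceded and followed by a vigorous-shake marker, daily-living bouts in
#' the gaps, and rest elsewhere. Sessions in the first half of a
#' participant's schedule are tagged `nMTE` (natural execution), the rest
#' `sMTE` (scripted), mirroring the two-week collection phases.
#'
#' @param cfg a [sim_config()].
#' @param participant 1-based participant index.
#' @param session 1-based session index.
#' @return list with `recording` (a [raw_recording()]) and `sidecar`
#'   (data.frame: kind, label, wrist, phase_mode, start_sample,
#'   end_sample; 0-based half-open sample intervals).
#' @export
simulate_session <- function(cfg, participant = 1L, session = 1L) {
  validate_sim_config(cfg)
  set.seed(session_seed(cfg$seed, participant, session))
  rate <- cfg$sampling_rate
  phase_mode <- if (session <= ceiling(cfg$sessions_per_participant / 2)) "nMTE" else "sMTE"

  # Medication bout plan: classes x wrists, honoring the per-wrist split.
  plan <- data.frame(label = character(0), wrist = character(0))
  for (cl in c("methadone", "buprenorphine")) {
    w <- rep(names(cfg$per_wrist_split), times = cfg$per_wrist_split)
    if (length(w))
      plan <- rbind(plan, data.frame(label = cl, wrist = w))
  }
  if (nrow(plan)) plan <- plan[sample.int(nrow(plan)), , drop = FALSE]

  n_daily <- cfg$daily_bouts_per_session
  daily_acts <- if (n_daily > 0)
    sample(names(cfg$daily_activity_mix), n_daily, replace = TRUE,
           prob = cfg$daily_activity_mix) else character(0)

  # Interleave: daily bouts are distributed over the gaps between
  # medication bouts (and before/after the protocol).
  n_med <- nrow(plan)
  slot_of_daily <- if (n_daily > 0) sort(sample.int(n_med + 1L, n_daily,
                                                    replace = TRUE)) else integer(0)

  templates <- list(
    methadone = medication_template("methadone", cfg$class_separability),
    buprenorphine = medication_template("buprenorphine", cfg$class_separability))

  chunks <- list()
  sidecar <- list()
  pos <- 0L  # current sample count (0-based next start)
  gap <- function(w = "right") {
    d <- stats::runif(1, cfg$inter_bout_gap_range[1], cfg$inter_bout_gap_range[2])
    render_rest(d, cfg, w)
  }
  push <- function(x) { chunks[[length(chunks) + 1L]] <<- x; pos <<- pos + ncol(x); invisible(NULL) }
  mark <- function(kind, label, wrist, start, end) {
    sidecar[[length(sidecar) + 1L]] <<- data.frame(
      kind = kind, label = label, wrist = wrist, phase_mode = phase_mode,
      start_sample = start, end_sample = end)
  }
  emit_daily <- function(k) {
    act <- daily_acts[k]
    w <- sample(c("left", "right"), 1L)
    d <- stats::runif(1, 1.5, 5)
    tr <- render_gesture(daily_template(act), d, w, rate, cfg$noise_sd)
    s0 <- pos; push(tr)
    mark("bout", paste0("daily:", act), w, s0, pos)
  }

  push(gap())
  di <- 1L
  for (slot in seq_len(n_med + 1L)) {
    while (di <= n_daily && slot_of_daily[di] == slot) {
      emit_daily(di); push(gap()); di <- di + 1L
    }
    if (slot > n_med) break
    lbl <- plan$label[slot]; w <- plan$wrist[slot]
    # shakes immediately bracket the gesture (short grip pause only), so
    # the inter-marker span delimits the bout to within a fraction of a
    # second
    pause <- function() render_rest(stats::runif(1, 0.05, 0.15), cfg, w)
    sh1 <- render_shake(cfg, w); s0 <- pos; push(sh1); mark("shake", "", w, s0, pos)
    push(pause())
    d <- draw_durations(1L, lbl, cfg)
    tr <- render_gesture(templates[[lbl]], d, w, rate, cfg$noise_sd,
                         duration_range = cfg$duration_range)
    b0 <- pos; push(tr); mark("bout", lbl, w, b0, pos)
    push(pause())
    sh2 <- render_shake(cfg, w); s0 <- pos; push(sh2); mark("shake", "", w, s0, pos)
    push(gap(w))
  }

  accel <- t(do.call(cbind, chunks))
  n <- nrow(accel)
  start <- cfg$session_start +
    ((participant - 1L) * 86400 + (session - 1L) * 7200)
  rec <- raw_recording(
    participant_id = sprintf("P%02d", participant),
    session_id = sprintf("S%02d", session),
    sampling_rate = rate,
    timestamps_ms = round((seq_len(n) - 1L) * 1000 / rate),
    accel = accel,
    start_time = start)
  sc <- if (length(sidecar)) do.call(rbind, sidecar) else
    data.frame(kind = character(0), label = character(0), wrist = character(0),
               phase_mode = character(0), start_sample = integer(0),
               end_sample = integer(0))
  sc <- sc[order(sc$start_sample), , drop = FALSE]
  rownames(sc) <- NULL
  list(recording = rec, sidecar = sc)
}

#' Simulate a full cohort and write it to disk
#'
#' Writes one raw CSV (`<participant>_<session>.csv`, dialect
#' `hour,minute,second,millisecond,day,month,year,ax,ay,az`) and one
#' ground-truth sidecar CSV per recording, plus a YAML manifest with
#' per-participant and cohort totals (recordings, samples, hours) and
#' per-file checksums.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (also written to `manifest.yaml`).
#' @export
simulate_cohort <- function(cfg, out_dir) {
  validate_sim_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  recs <- list()
  for (p in seq_len(cfg$n_participants)) {
    for (s in seq_len(cfg$sessions_per_participant)) {
      sim <- simulate_session(cfg, p, s)
      stem <- sprintf("P%02d_S%02d", p, s)
      raw_path <- file.path(out_dir, paste0(stem, ".csv"))
      side_path <- file.path(out_dir, paste0(stem, "_sidecar.csv"))
      write_raw_csv(sim$recording, raw_path)
      data.table::fwrite(sim$sidecar, side_path)
      n <- nrow(sim$recording$accel)
      recs[[stem]] <- list(
        participant_id = sim$recording$participant_id,
        session_id = sim$recording$session_id,
        raw = basename(raw_path), sidecar = basename(side_path),
        samples = n,
        duration_s = round(n / cfg$sampling_rate, 2),
        n_bouts = sum(sim$sidecar$kind == "bout"),
        checksum = unname(tools::md5sum(raw_path)))
    }
  }
  per_part <- lapply(split(recs, vapply(recs, `[[`, "", "participant_id")),
                     function(rr) list(
                       recordings = length(rr),
                       samples = sum(vapply(rr, `[[`, 0, "samples")),
                       hours = round(sum(vapply(rr, `[[`, 0, "duration_s")) / 3600, 4)))
  manifest <- list(
    sampling_rate = cfg$sampling_rate,
    n_participants = cfg$n_participants,
    sessions_per_participant = cfg$sessions_per_participant,
    cohort = list(
      recordings = length(recs),
      samples = sum(vapply(recs, `[[`, 0, "samples")),
      hours = round(sum(vapply(recs, `[[`, 0, "duration_s")) / 3600, 4)),
    participants = per_part,
    recordings = recs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Simulate a cohort in memory
#'
#' Like [simulate_cohort()] but returns the sessions as R objects instead
#' of writing CSVs; used by the end-to-end pipeline and benchmarks.
#'
#' @param cfg a [sim_config()].
#' @return list of `simulate_session()` results, named `P.._S..`.
#' @export
simulate_cohort_memory <- function(cfg) {
  validate_sim_config(cfg)
  out <- list()
  for (p in seq_len(cfg$n_participants))
    for (s in seq_len(cfg$sessions_per_participant))
      out[[sprintf("P%02d_S%02d", p, s)]] <- simulate_session(cfg, p, s)
  out
}
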