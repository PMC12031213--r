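# Kinematic templates: a gesture is an ordered list of phases, each with a
# start/end wrist orientation (unit gravity direction in the sensor frame),
# a smooth movement-acceleration bump, and an optional oscillatory
# component (tremor-like jitter for tearing/typing, rhythmic swing for
# waving/shaking).

GRAVITY <- 9.81

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalized")
  v / n
}

# Spherical interpolation between unit vectors; degenerates to identity for
# (near-)parallel endpoints.
slerp <- function(a, b, t) {
  d <- max(-1, min(1, sum(a * b)))
  th <- acos(d)
  if (th < 1e-8) return(matrix(rep(a, length(t)), nrow = 3))
  s <- sin(th)
  sapply(t, function(u) (sin((1 - u) * th) * a + sin(u * th) * b) / s)
}

smoothstep <- function(u) u * u * (3 - 2 * u)

#' Construct a kinematic phase
#'
#' @param name phase name.
#' @param duration_fraction fraction of the gesture duration in (0, 1].
#' @param orient_from,orient_to unit gravity directions (sensor frame) at
#'   the phase boundaries.
#' @param peak_accel peak of the smooth movement-acceleration bump, m/s^2.
#' @param accel_dir direction of the movement bump (unit 3-vector).
#' @param osc_amp,osc_freq amplitude (m/s^2) and frequency (Hz) of an
#'   optional oscillatory component riding on the phase.
#' @return a `kinematic_phase` list.
#' @export
kinematic_phase <- function(name, duration_fraction, orient_from, orient_to,
                            peak_accel = 0, accel_dir = c(1, 0, 0),
                            osc_amp = 0, osc_freq = 0) {
  stopifnot(duration_fraction > 0, duration_fraction <= 1)
  of <- unit(orient_from); ot <- unit(orient_to)
  if (abs(sqrt(sum(of^2)) - 1) > 1e-9 || abs(sqrt(sum(ot^2)) - 1) > 1e-9)
    stop("orientation endpoints must be unit norm")
  structure(list(name = name, duration_fraction = duration_fraction,
                 orient_from = of, orient_to = ot,
                 peak_accel = peak_accel, accel_dir = unit(accel_dir),
                 osc_amp = osc_amp, osc_freq = osc_freq),
            class = "kinematic_phase")
}

#' Construct a gesture template
#'
#' @param class_label gesture class (`"methadone"`, `"buprenorphine"`, or
#'   `"daily:<activity>"`).
#' @param phases list of [kinematic_phase()]s; duration fractions must sum
#'   to 1 within 1e-9.
#' @return a `gesture_template` list.
#' @export
gesture_template <- function(class_label, phases) {
  fr <- vapply(phases, `[[`, numeric(1), "duration_fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("phase duration fractions must sum to 1 (got ", sum(fr), ")")
  structure(list(class_label = class_label, phases = phases),
            class = "gesture_template")
}

# Both medication gestures share a five-phase skeleton with identical
# duration fractions, so templates can be blended phase-wise:
#   reach -> prepare -> raise -> ingest -> lower
# "prepare" is cap-unscrewing (near-static on the watch hand) for
# methadone and packet-tearing (high-frequency jitter) for buprenorphine.
medication_phase_fractions <- c(reach = 0.15, prepare = 0.20, raise = 0.20,
                                ingest = 0.25, lower = 0.20)

methadone_template_full <- function() {
  fr <- medication_phase_fractions
  rest <- c(0, 0, 1)              # watch face up, forearm horizontal
  fwd  <- unit(c(0.35, 0.1, 0.93))
  tilt <- unit(c(0.25, -0.78, 0.57))  # bottle raised, wrist rotated to pour
  gesture_template("methadone", list(
    kinematic_phase("reach",   fr[["reach"]],   rest, fwd,
                    peak_accel = 1.6, accel_dir = c(1, 0, -0.3)),
    kinematic_phase("prepare", fr[["prepare"]], fwd, fwd,
                    peak_accel = 0.15, accel_dir = c(0, 1, 0)),
    kinematic_phase("raise",   fr[["raise"]],   fwd, tilt,
                    peak_accel = 2.2, accel_dir = c(0.2, -1, 0.4)),
    kinematic_phase("ingest",  fr[["ingest"]],  tilt, tilt,
                    peak_accel = 0.5, accel_dir = c(0, -1, 0),
                    osc_amp = 0.35, osc_freq = 1.2),
    kinematic_phase("lower",   fr[["lower"]],   tilt, rest,
                    peak_accel = 1.8, accel_dir = c(-1, 0.4, 0))
  ))
}

buprenorphine_template_full <- function() {
  fr <- medication_phase_fractions
  rest <- c(0, 0, 1)
  fwd  <- unit(c(0.15, 0.35, 0.92))
  up   <- unit(c(-0.55, 0.45, 0.70))  # film brought to the mouth, palm in
  gesture_template("buprenorphine", list(
    kinematic_phase("reach",   fr[["reach"]],   rest, fwd,
                    peak_accel = 1.3, accel_dir = c(0.8, 0.5, 0)),
    kinematic_phase("prepare", fr[["prepare"]], fwd, fwd,
                    peak_accel = 0.5, accel_dir = c(1, -1, 0),
                    osc_amp = 1.8, osc_freq = 8),   # tearing the packet
    kinematic_phase("raise",   fr[["raise"]],   fwd, up,
                    peak_accel = 2.0, accel_dir = c(-0.6, 0.8, 0.2)),
    kinematic_phase("ingest",  fr[["ingest"]],  up, up,
                    peak_accel = 0.4, accel_dir = c(0.2, 1, 0.1)),
    kinematic_phase("lower",   fr[["lower"]],   up, rest,
                    peak_accel = 1.6, accel_dir = c(0.7, -0.7, 0))
  ))
}

# Phase-wise blend of two templates sharing a skeleton: slerp orientations,
# lerp scalar parameters. t = 0 gives a, t = 1 gives b.
blend_templates <- function(a, b, t, class_label) {
  stopifnot(length(a$phases) == length(b$phases))
  phases <- mapply(function(pa, pb) {
    kinematic_phase(
      pa$name, pa$duration_fraction,
      slerp(pa$orient_from, pb$orient_from, t)[, 1],
      slerp(pa$orient_to, pb$orient_to, t)[, 1],
      peak_accel = (1 - t) * pa$peak_accel + t * pb$peak_accel,
      accel_dir = unit((1 - t) * pa$accel_dir + t * pb$accel_dir),
      osc_amp = (1 - t) * pa$osc_amp + t * pb$osc_amp,
      osc_freq = (1 - t) * pa$osc_freq + t * pb$osc_freq)
  }, a$phases, b$phases, SIMPLIFY = FALSE)
  gesture_template(class_label, phases)
}

#' Medication gesture template at a given class separability
#'
#' At separability 1 the methadone (liquid) and buprenorphine (film)
#' templates are fully distinct; at 0 both collapse onto their common mean
#' so the class-mean traces coincide.
#'
#' @param class `"methadone"` or `"buprenorphine"`.
#' @param separability dimensionless in \[0,1\].
#' @return a `gesture_template`.
#' @export
medication_template <- function(class = c("methadone", "buprenorphine"),
                                separability = 1) {
  class <- match.arg(class)
  m <- methadone_template_full(); b <- buprenorphine_template_full()
  mid <- blend_templates(m, b, 0.5, "midpoint")
  full <- if (class == "methadone") m else b
  blend_templates(mid, full, separability, class)
}

#' Daily-living activity templates
#'
#' `drinking` clones the full methadone motion (drinking water from a small
#' bottle is kinematically identical to taking liquid medication) and is
#' the designated confounder; the rest are generic wrist activities.
#'
#' @param activity one of `"drinking"`, `"typing"`, `"reaching"`,
#'   `"waving"`, `"rest"`.
#' @return a `gesture_template` with label `daily:<activity>`.
#' @export
daily_template <- function(activity = c("drinking", "typing", "reaching",
                                        "waving", "rest")) {
  activity <- match.arg(activity)
  rest <- c(0, 0, 1)
  lbl <- paste0("daily:", activity)
  tpl <- switch(activity,
    drinking = {
      t <- methadone_template_full()
      gesture_template(lbl, t$phases)
    },
    typing = gesture_template(lbl, list(
      kinematic_phase("type", 1, unit(c(0.1, 0.05, 0.99)),
                      unit(c(0.1, 0.05, 0.99)),
                      peak_accel = 0.2, accel_dir = c(0, 0, 1),
                      osc_amp = 0.9, osc_freq = 6))),
    reaching = gesture_template(lbl, list(
      kinematic_phase("out", 0.5, rest, unit(c(0.9, 0.2, 0.38)),
                      peak_accel = 2.5, accel_dir = c(1, 0, 0)),
      kinematic_phase("back", 0.5, unit(c(0.9, 0.2, 0.38)), rest,
                      peak_accel = 2.5, accel_dir = c(-1, 0, 0)))),
    waving = gesture_template(lbl, list(
      kinematic_phase("wave", 1, unit(c(0.7, 0, 0.71)),
                      unit(c(-0.5, 0.2, 0.84)),
                      peak_accel = 1.0, accel_dir = c(1, 1, 0),
                      osc_amp = 2.5, osc_freq = 2))),
    rest = gesture_template(lbl, list(
      kinematic_phase("still", 1, rest, rest))))
  tpl
}

#' Render a gesture template to a 3-channel acceleration trace
#'
#' The trace is the gravity direction slerped through the phase orientation
#' endpoints (scaled to 9.81 m/s^2), plus each phase's movement bump
#' `peak * sin(pi u)^2` along its direction, plus any oscillatory
#' component, plus white Gaussian sensor noise. A left-wrist rendering is
#' the right-wrist rendering with the x and z channels negated (the
#' package's fixed handedness mirroring).
#'
#' Randomness (noise, oscillation phase) is taken from R's global RNG;
#' seed the RNG for reproducible traces.
#'
#' @param template a [gesture_template()].
#' @param duration gesture duration in seconds.
#' @param wrist `"right"` or `"left"`.
#' @param rate sampling rate, Hz.
#' @param noise_sd sensor noise standard deviation, m/s^2.
#' @param duration_range permitted duration range (rejected outside it);
#'   `NULL` skips the check.
#' @return a 3 x n matrix (rows x, y, z), n = `round(duration * rate)`.
#' @export
render_gesture <- function(template, duration, wrist = c("right", "left"),
                           rate = 100, noise_sd = 0.05,
                           duration_range = NULL) {
  wrist <- match.arg(wrist)
  if (!is.null(duration_range) &&
      (duration < duration_range[1] || duration > duration_range[2]))
    stop(sprintf("duration %.3f s outside allowed range [%.3f, %.3f] s",
                 duration, duration_range[1], duration_range[2]))
  n <- round(duration * rate)
  if (n < 1) stop("duration too short for one sample at this rate")
  fr <- vapply(template$phases, `[[`, numeric(1), "duration_fraction")
  # Integer sample counts per phase, preserving the total exactly.
  edges <- round(cumsum(c(0, fr)) * n)
  out <- matrix(0, 3, n)
  t_global <- (seq_len(n) - 0.5) / rate
  for (i in seq_along(template$phases)) {
    ph <- template$phases[[i]]
    i0 <- edges[i] + 1L; i1 <- edges[i + 1L]
    if (i1 < i0) next
    m <- i1 - i0 + 1L
    u <- (seq_len(m) - 0.5) / m
    g <- GRAVITY * slerp(ph$orient_from, ph$orient_to, smoothstep(u))
    bump <- ph$peak_accel * sin(pi * u)^2
    mv <- outer(ph$accel_dir, bump)
    if (ph$osc_amp > 0) {
      phase0 <- stats::runif(1, 0, 2 * pi)
      osc <- ph$osc_amp * sin(2 * pi * ph$osc_freq * t_global[i0:i1] + phase0) *
        sin(pi * u)  # taper so the oscillation starts/ends smoothly
      mv <- mv + outer(ph$accel_dir, osc)
    }
    out[, i0:i1] <- g + mv
  }
  if (noise_sd > 0)
    out <- out + matrix(stats::rnorm(3L * n, sd = noise_sd), 3, n)
  if (wrist == "left") {
    out[1, ] <- -out[1, ]
    out[3, ] <- -out[3, ]
  }
  rownames(out) <- c("ax", "ay", "az")
  out
}

# Vigorous wrist shake: a tapered sinusoidal burst dominating the movement
# band, used as the labeling delimiter around every medication bout.
render_shake <- function(cfg, wrist = "right") {
  n <- round(cfg$shake_duration * cfg$sampling_rate)
  t <- (seq_len(n) - 0.5) / cfg$sampling_rate
  # flat-top (Tukey) envelope with 10% ramps: the shake is at full
  # vigor almost immediately, making its extent sharply delimited
  u <- (seq_len(n) - 0.5) / n
  ramp <- 0.1
  env <- pmin(1, pmin(u, 1 - u) / ramp)
  env <- sin(env * pi / 2)
  phase0 <- stats::runif(1, 0, 2 * pi)
  burst <- cfg$shake_amplitude * env * sin(2 * pi * cfg$shake_frequency * t + phase0)
  out <- rbind(ax = 0.8 * burst, ay = 0.5 * burst, az = GRAVITY + 0.3 * burst)
  if (cfg$noise_sd > 0)
    out <- out + matrix(stats::rnorm(3L * n, sd = cfg$noise_sd), 3, n)
  if (wrist == "left") { out[1, ] <- -out[1, ]; out[3, ] <- -out[3, ] }
  out
}

# Quiet rest filler between protocol elements.
render_rest <- function(duration, cfg, wrist = "right") {
  render_gesture(daily_template("rest"), duration, wrist,
                 rate = cfg$sampling_rate, noise_sd = cfg$noise_sd)
}
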