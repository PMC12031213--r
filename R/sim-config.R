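#' Simulation configuration for a synthetic smartwatch cohort
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' the lab protocol the package targets: 16 participants, ~10 sessions each,
#' 20 medication gestures per session (10 oral-liquid methadone, 10
#' sublingual buprenorphine film; 5 per wrist per type), gesture durations
#' in \[2.5, 11\] s, a vigorous wrist shake before and after every
#' medication bout, and daily-living activity filling the gaps.
#'
#' Durations are drawn as `2.5 + 8.5 * Beta(2, b)` seconds with a per-class
#' `b` calibrated so that a 4-s window retains 96% of methadone and 95% of
#' buprenorphine bouts (the class medians are then 3.03 s and 3.06 s).
#'
#' @param n_participants number of participants in the cohort.
#' @param sessions_per_participant recordings per participant.
#' @param gestures_per_session_per_class medication bouts per class per
#'   session (default 10, i.e. 20 medication bouts per session).
#' @param per_wrist_split integer vector `c(left, right)` counts per class
#'   per session; must sum to `gestures_per_session_per_class`.
#' @param sampling_rate sensor rate in Hz.
#' @param duration_range allowed bout duration range in seconds.
#' @param duration_beta_shape2 per-class second Beta shape parameter,
#'   named vector for classes `methadone` and `buprenorphine`.
#' @param duration_median_per_class implied per-class median duration in
#'   seconds (informational; derived from the Beta calibration).
#' @param shake_amplitude peak shake acceleration, m/s^2.
#' @param shake_frequency shake oscillation frequency, Hz.
#' @param shake_duration shake burst length, seconds.
#' @param inter_bout_gap_range rest gap between protocol elements, seconds.
#' @param daily_bouts_per_session daily-living bouts planted per session.
#' @param daily_activity_mix named numeric weights over the daily-living
#'   taxonomy `drinking`, `typing`, `reaching`, `waving`, `rest`.
#'   `drinking` deliberately shares the methadone motion template, so its
#'   weight is the difficulty dial for medication-vs-daily discrimination.
#' @param noise_sd additive Gaussian sensor noise, m/s^2.
#' @param class_separability in \[0,1\]; 1 renders the two medication
#'   templates fully distinct, 0 collapses them onto their common mean.
#' @param session_start POSIXct-parsable start datetime of the first
#'   session; wall-clock timestamps are laid on a 10 ms grid from here.
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 16,
                       sessions_per_participant = 10,
                       gestures_per_session_per_class = 10,
                       per_wrist_split = c(left = 5, right = 5),
                       sampling_rate = 100,
                       duration_range = c(2.5, 11),
                       duration_beta_shape2 = c(methadone = 25.3312,
                                                buprenorphine = 23.9465),
                       duration_median_per_class = c(methadone = 3.035,
                                                     buprenorphine = 3.064),
                       shake_amplitude = 15,
                       shake_frequency = 4,
                       shake_duration = 1,
                       inter_bout_gap_range = c(1.5, 4),
                       daily_bouts_per_session = gestures_per_session_per_class * 2L,
                       daily_activity_mix = c(drinking = 0.15, typing = 0.30,
                                              reaching = 0.25, waving = 0.15,
                                              rest = 0.15),
                       noise_sd = 0.05,
                       class_separability = 1,
                       session_start = "2024-03-04 09:00:00",
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    sessions_per_participant = as.integer(sessions_per_participant),
    gestures_per_session_per_class = as.integer(gestures_per_session_per_class),
    per_wrist_split = per_wrist_split,
    sampling_rate = sampling_rate,
    duration_range = duration_range,
    duration_beta_shape2 = duration_beta_shape2,
    duration_median_per_class = duration_median_per_class,
    shake_amplitude = shake_amplitude,
    shake_frequency = shake_frequency,
    shake_duration = shake_duration,
    inter_bout_gap_range = inter_bout_gap_range,
    daily_bouts_per_session = as.integer(daily_bouts_per_session),
    daily_activity_mix = daily_activity_mix,
    noise_sd = noise_sd,
    class_separability = class_separability,
    session_start = as.POSIXct(session_start, tz = "UTC"),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_participants < 1L || cfg$sessions_per_participant < 1L)
    stop("n_participants and sessions_per_participant must be >= 1")
  if (cfg$gestures_per_session_per_class < 0L)
    stop("gestures_per_session_per_class must be >= 0")
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0")
  dr <- cfg$duration_range
  if (length(dr) != 2L || dr[1] <= 0 || dr[1] >= dr[2])
    stop("duration_range must satisfy 0 < lower < upper")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$class_separability < 0 || cfg$class_separability > 1)
    stop("class_separability must lie in [0, 1]")
  if (sum(cfg$per_wrist_split) != cfg$gestures_per_session_per_class)
    stop("per_wrist_split must sum to gestures_per_session_per_class")
  if (any(cfg$per_wrist_split < 0)) stop("per_wrist_split counts must be >= 0")
  if (any(cfg$daily_activity_mix < 0) || sum(cfg$daily_activity_mix) <= 0)
    stop("daily_activity_mix weights must be non-negative and not all zero")
  if (cfg$daily_bouts_per_session < 0L)
    stop("daily_bouts_per_session must be >= 0")
  if (cfg$shake_amplitude <= 0 || cfg$shake_frequency <= 0 ||
      cfg$shake_duration <= 0)
    stop("shake parameters must be positive")
  invisible(cfg)
}

# Deterministic per-session seed derived from the master seed. Kept below
# 2^31 so it is a valid R integer.
session_seed <- function(seed, participant, session) {
  as.integer((as.double(seed) * 2654435L +
              participant * 97003L + session * 641L) %% 2147483647)
}

#' Draw medication bout durations for one class
#'
#' @param n number of draws.
#' @param class `"methadone"` or `"buprenorphine"`.
#' @param cfg a [sim_config()].
#' @return durations in seconds, all inside `cfg$duration_range`.
#' @export
draw_durations <- function(n, class, cfg) {
  b <- cfg$duration_beta_shape2[[class]]
  dr <- cfg$duration_range
  dr[1] + diff(dr) * stats::rbeta(n, 2, b)
}
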