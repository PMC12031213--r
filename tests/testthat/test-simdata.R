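test_that("rendered gestures have exact sample counts and are deterministic", {
  tpl <- medication_template("methadone", 1)
  set.seed(11); tr1 <- render_gesture(tpl, 4.0, "right", rate = 100)
  expect_identical(dim(tr1), c(3L, 400L))
  set.seed(11); tr2 <- render_gesture(tpl, 4.0, "right", rate = 100)
  expect_identical(tr1, tr2)
  # sample count follows round(duration * rate) at awkward durations too
  for (d in c(2.5, 3.337, 10.999))
    expect_equal(ncol(render_gesture(tpl, d, rate = 100)), round(d * 100))
})

test_that("a static noiseless template renders pure gravity", {
  tpl <- gesture_template("daily:rest", list(
    kinematic_phase("still", 1, c(0, 0, 1), c(0, 0, 1))))
  tr <- render_gesture(tpl, 2, "right", rate = 100, noise_sd = 0)
  expect_equal(max(abs(tr[1, ])), 0)
  expect_equal(max(abs(tr[2, ])), 0)
  expect_true(all(abs(tr[3, ] - 9.81) < 1e-12))
  expect_true(all(abs(sqrt(colSums(tr^2)) - 9.81) < 1e-9))
})

test_that("durations outside the configured range are rejected", {
  tpl <- medication_template("methadone", 1)
  expect_error(render_gesture(tpl, 1.0, duration_range = c(2.5, 11)),
               "outside allowed range")
  expect_error(render_gesture(tpl, 12, duration_range = c(2.5, 11)),
               "outside allowed range")
})

test_that("left-wrist rendering mirrors the x and z channels", {
  tpl <- medication_template("buprenorphine", 1)
  set.seed(5); r <- render_gesture(tpl, 3, "right", noise_sd = 0)
  set.seed(5); l <- render_gesture(tpl, 3, "left", noise_sd = 0)
  expect_equal(l[1, ], -r[1, ])
  expect_equal(l[2, ], r[2, ])
  expect_equal(l[3, ], -r[3, ])
})

test_that("a session honors the protocol bout counts and wrist split", {
  cfg <- tiny_sim_config(seed = 3)
  s <- simulate_session(cfg, 1, 1)
  bouts <- s$sidecar[s$sidecar$kind == "bout", ]
  med <- bouts[bouts$label %in% c("methadone", "buprenorphine"), ]
  expect_equal(nrow(med), 20L)
  expect_equal(sum(med$label == "methadone"), 10L)
  expect_equal(sum(med$label == "buprenorphine"), 10L)
  for (cl in c("methadone", "buprenorphine")) {
    expect_equal(sum(med$label == cl & med$wrist == "left"), 5L)
    expect_equal(sum(med$label == cl & med$wrist == "right"), 5L)
  }
  # bouts strictly ordered and non-overlapping
  expect_true(all(diff(bouts$start_sample) > 0))
  expect_true(all(bouts$end_sample[-nrow(bouts)] <= bouts$start_sample[-1]))
  # every medication bout is bracketed by a shake before and after
  shakes <- s$sidecar[s$sidecar$kind == "shake", ]
  for (i in seq_len(nrow(med))) {
    expect_true(any(shakes$end_sample <= med$start_sample[i] &
                    shakes$end_sample >= med$start_sample[i] - 100))
    expect_true(any(shakes$start_sample >= med$end_sample[i] &
                    shakes$start_sample <= med$end_sample[i] + 100))
  }
})

test_that("an empty medication protocol yields pure daily-living signal", {
  cfg <- sim_config(n_participants = 1, sessions_per_participant = 1,
                    gestures_per_session_per_class = 0,
                    per_wrist_split = c(left = 0, right = 0), seed = 2)
  s <- simulate_session(cfg, 1, 1)
  expect_equal(sum(s$sidecar$kind == "shake"), 0L)
  labs <- s$sidecar$label[s$sidecar$kind == "bout"]
  expect_true(all(grepl("^daily:", labs)))
})

test_that("bout durations respect the configured range and medians", {
  cfg <- sim_config(seed = 42)
  set.seed(42)
  for (cl in c("methadone", "buprenorphine")) {
    d <- draw_durations(2000, cl, cfg)
    expect_true(all(d >= 2.5 & d <= 11))
    expect_lt(abs(median(d) - cfg$duration_median_per_class[[cl]]) /
                cfg$duration_median_per_class[[cl]], 0.10)
  }
})

test_that("class separability dial controls template distinctness", {
  d <- 4; n <- round(d * 100)
  mean_trace <- function(cls, sep) {
    tpl <- medication_template(cls, sep)
    set.seed(1)  # same oscillation phases for both classes
    render_gesture(tpl, d, "right", noise_sd = 0)
  }
  hi <- sqrt(sum((mean_trace("methadone", 1) - mean_trace("buprenorphine", 1))^2) / n)
  lo <- sqrt(sum((mean_trace("methadone", 0) - mean_trace("buprenorphine", 0))^2) / n)
  expect_gt(hi, 0.5)   # clearly separated templates at separability 1
  expect_lt(lo, 1e-9)  # coincident class means at separability 0
})

test_that("cohort simulation writes a consistent, deterministic manifest", {
  cfg <- sim_config(n_participants = 2, sessions_per_participant = 2, seed = 9)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  man1 <- simulate_cohort(cfg, dir1)
  man2 <- simulate_cohort(cfg, dir2)
  expect_equal(man1$cohort$recordings, 4L)
  expect_length(man1$recordings, 4L)
  # directory listing cross-check
  expect_equal(sort(unname(vapply(man1$recordings, `[[`, "", "raw"))),
               sort(grep("_sidecar|manifest", list.files(dir1, "\\.csv$"),
                         value = TRUE, invert = TRUE)))
  # totals equal the sum of per-recording counts; rows match sample counts
  per_rec <- vapply(man1$recordings, `[[`, 0, "samples")
  expect_equal(man1$cohort$samples, sum(per_rec))
  for (nm in names(man1$recordings)) {
    rec <- man1$recordings[[nm]]
    n_rows <- nrow(data.table::fread(file.path(dir1, rec$raw)))
    expect_equal(n_rows, rec$samples)
    expect_equal(rec$samples, round(rec$duration_s * cfg$sampling_rate))
  }
  # byte-identical outputs across runs with the same config
  expect_identical(vapply(man1$recordings, `[[`, "", "checksum"),
                   vapply(man2$recordings, `[[`, "", "checksum"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_participants = 0), "must be >= 1")
  expect_error(sim_config(duration_range = c(5, 3)), "lower < upper")
  expect_error(sim_config(class_separability = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(per_wrist_split = c(left = 3, right = 3)),
               "must sum to")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})
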