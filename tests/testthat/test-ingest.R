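make_toy_csv <- function(path, n = 3) {
  df <- data.frame(hour = 9, minute = 0, second = 0,
                   millisecond = seq(0, by = 10, length.out = n),
                   day = 4, month = 3, year = 2024,
                   ax = seq_len(n) * 0.1, ay = -seq_len(n) * 0.2,
                   az = rep(9.81, n))
  write.csv(df, path, row.names = FALSE)
  df
}

test_that("a toy raw CSV round-trips verbatim", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_toy_csv(path)
  rec <- read_raw_csv(path)
  expect_s3_class(rec, "raw_recording")
  expect_equal(nrow(rec$accel), 3L)
  expect_equal(unname(rec$accel[, 1]), df$ax)
  expect_equal(unname(rec$accel[, 3]), df$az)
  expect_equal(rec$timestamps_ms, c(0, 10, 20))
})

test_that("simulator output survives the write/read round trip", {
  s <- simulate_session(tiny_sim_config(seed = 4), 1, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(s$recording, path)
  rec <- read_raw_csv(path)
  expect_lt(max(abs(rec$accel - s$recording$accel)), 1e-6)
  expect_identical(rec$timestamps_ms, s$recording$timestamps_ms)
})

test_that("malformed raw CSVs produce named, early errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_toy_csv(path)
  # missing column
  write.csv(df[, setdiff(names(df), "ay")], path, row.names = FALSE)
  expect_error(read_raw_csv(path), "missing column\\(s\\): ay")
  # repeated timestamp
  df2 <- df; df2$millisecond[2] <- 0
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_raw_csv(path), "non-monotone")
  # empty file
  writeLines(paste(medgest:::RAW_COLUMNS, collapse = ","), path)
  expect_error(read_raw_csv(path), "empty")
  expect_error(read_raw_csv(withr::local_tempfile(fileext = ".csv")),
               "not found")
})

test_that("a quiet recording yields no shake markers", {
  rec <- raw_recording("P01", "S01", 100, seq(0, by = 10, length.out = 500),
                       cbind(rep(0, 500), rep(0, 500), rep(9.81, 500)))
  expect_equal(nrow(detect_shake_markers(rec)), 0L)
})

test_that("an unreachable threshold yields no markers", {
  s <- simulate_session(tiny_sim_config(seed = 6), 1, 1)
  expect_equal(nrow(detect_shake_markers(s$recording, threshold = Inf)), 0L)
})

test_that("recordings shorter than the RMS window are rejected", {
  rec <- raw_recording("P01", "S01", 100, c(0, 10, 20),
                       cbind(0:2, 0:2, rep(9.81, 3)))
  expect_error(detect_shake_markers(rec), "too short")
})

test_that("planted shakes are recovered exactly with tight boundaries", {
  for (seed in 1:8) {
    s <- simulate_session(tiny_sim_config(seed = seed), 1, 1)
    m <- detect_shake_markers(s$recording)
    sh <- s$sidecar[s$sidecar$kind == "shake", ]
    expect_equal(nrow(m), nrow(sh))            # no misses, no false alarms
    err <- pmax(abs(m$start_sample - sh$start_sample),
                abs(m$end_sample - sh$end_sample)) / 100
    expect_lte(max(err), 0.2)
  }
})

test_that("segmentation turns marker pairs into labeled bouts", {
  rec <- raw_recording("P01", "S01", 100, seq(0, by = 10, length.out = 1000),
                       cbind(rnorm(1000, 0, 0.01), rnorm(1000, 0, 0.01),
                             rep(9.81, 1000)))
  markers <- data.frame(start_sample = c(100L, 600L), end_sample = c(200L, 700L))
  ann <- data.frame(label = "methadone", wrist = "right")
  seg <- segment_bouts(rec, markers, ann)
  expect_equal(nrow(seg$bouts), 1L)
  expect_equal(seg$bouts$start_sample, 200L)
  expect_equal(seg$bouts$end_sample, 600L)
  expect_equal(seg$n_discarded, 0L)
  # all discarded
  seg2 <- segment_bouts(rec, markers, data.frame(label = "discard"))
  expect_equal(nrow(seg2$bouts), 0L)
  expect_equal(seg2$n_discarded, 1L)
  # overlapping markers are an integrity error
  bad <- data.frame(start_sample = c(100L, 150L), end_sample = c(200L, 300L))
  expect_error(segment_bouts(rec, bad, ann), "overlapping")
})

test_that("segmentation recovers all planted medication bouts from markers", {
  s <- simulate_session(tiny_sim_config(seed = 12), 1, 1)
  m <- detect_shake_markers(s$recording)
  gt <- s$sidecar[s$sidecar$kind == "bout" &
                  !grepl("^daily:", s$sidecar$label), ]
  ann <- data.frame(label = gt$label, wrist = gt$wrist,
                    phase_mode = gt$phase_mode)
  seg <- segment_bouts(s$recording, m, ann)
  expect_equal(nrow(seg$bouts), nrow(gt))
  expect_equal(seg$bouts$label, gt$label)
  err <- pmax(abs(seg$bouts$start_sample - gt$start_sample),
              abs(seg$bouts$end_sample - gt$end_sample)) / 100
  expect_lte(max(err), 0.2)
})
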