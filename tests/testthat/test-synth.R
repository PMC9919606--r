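# synthetic generator: beat trains, noise, cohorts, ground-truth contracts

test_that("metronomic 60 bpm yields exactly one beat per second of baseline", {
  st <- clean_train_60()
  r <- st$truth$fiducials$R_peak
  base <- st$truth$epochs[st$truth$epochs$label == "baseline", ]
  expect_equal(sum(r >= base$start_sample & r < base$end_sample), 300)
})

test_that("generation is deterministic given seed and parameters", {
  bm <- beat_model(hr_bpm = 72, rr_jitter = 0.03)
  lay <- protocol_layout(cpt_s = 90)
  a <- synth_beat_train(bm, lay, effect_spec(), seed = 5)
  b <- synth_beat_train(bm, lay, effect_spec(), seed = 5)
  expect_identical(a$signal, b$signal)
  expect_identical(a$truth, b$truth)
  c <- synth_beat_train(bm, lay, effect_spec(), seed = 6)
  expect_false(identical(a$signal, c$signal))
})

test_that("identity effect leaves CPT beats identical to baseline beats", {
  st <- clean_train_60()
  fid <- st$truth$fiducials
  ep <- st$truth$epochs
  in_ep <- function(idx, lab) {
    e <- ep[ep$label == lab, ]
    idx >= e$start_sample & idx < e$end_sample
  }
  s_base <- st$signal[fid$S_peak[in_ep(fid$S_peak, "baseline")] + 1]
  s_cpt <- st$signal[fid$S_peak[in_ep(fid$S_peak, "cpt")] + 1]
  expect_equal(unique(round(s_base, 12)), unique(round(s_cpt, 12)))
})

test_that("ground truth is complete, ordered and inside the signal", {
  bm <- beat_model(hr_bpm = 80, rr_jitter = 0.03)
  st <- synth_beat_train(bm, protocol_layout(cpt_s = 70), effect_spec(),
                         seed = 3)
  fid <- st$truth$fiducials
  expect_false(anyNA(fid))
  for (col in names(fid)) expect_true(all(diff(fid[[col]]) > 0), info = col)
  ord <- c("P_onset", "P_peak", "P_offset", "R_onset", "R_peak", "S_peak",
           "R_offset", "T_onset", "T_peak", "T_offset")
  expect_true(all(apply(fid[, ord], 1, function(v) all(diff(v) > 0))))
  expect_true(all(fid >= 0 & fid < length(st$signal)))
  expect_true(all(is.finite(st$signal)))
  # amplitude bounded by the sum of wave amplitudes (plus the CPT shift)
  expect_lt(max(abs(st$signal)), sum(abs(bm$waves$amp)) + 0.05)
})

test_that("invalid beat models are rejected", {
  w <- default_waves()
  w$width[1] <- -0.01
  expect_error(beat_model(waves = w), "width")
  expect_error(beat_model(hr_bpm = 10), "range")
  w <- default_waves()
  w$center[2] <- -0.3 # Q before P
  expect_error(beat_model(waves = w), "ordered")
})

test_that("add_noise composes wander, powerline and white noise", {
  x <- numeric(100000)
  expect_identical(add_noise(x, zero_noise(), seed = 1), x)
  # 0.5 mV sinusoid RMS = 0.5/sqrt(2) over an integer number of cycles
  ns <- noise_spec(wander_amp = 0.5, wander_hz = 0.1, powerline_amp = 0,
                   broadband_sd = 0)
  y <- add_noise(x, ns, seed = 2, fs = 1000)
  expect_equal(sqrt(mean(y^2)), 0.5 / sqrt(2), tolerance = 0.01)
  expect_identical(add_noise(x, noise_spec(), seed = 3),
                   add_noise(x, noise_spec(), seed = 3))
  expect_error(noise_spec(wander_amp = -1), "range")
  expect_error(noise_spec(wander_hz = 0.7), "range")
})

test_that("cohorts have the right shape and participant-level variation", {
  co <- generate_cohort(n_participants = 36, n_sessions = 2, seed = 1)
  expect_equal(length(co), 72)
  expect_error(generate_cohort(n_participants = 0), "empty cohort")

  co1 <- generate_cohort(n_participants = 2, n_sessions = 1, seed = 8)
  expect_false(identical(co1$participants[[1]], co1$participants[[2]]))

  rr <- realize_recording(co1, 1)
  cpt_s <- co1$sessions$cpt_s[1]
  expect_equal(length(rr$recording$signal), round((300 + 120 + cpt_s + 120 + 300) * 1000))
  # morphology persists across sessions of one participant
  co2 <- generate_cohort(n_participants = 1, n_sessions = 2, seed = 8)
  expect_identical(co2$participants[[1]], co2$participants[[1]])
  # reproducible from (seed, parameters) alone
  rr_a <- realize_recording(generate_cohort(2, 2, seed = 9), 3)
  rr_b <- realize_recording(generate_cohort(2, 2, seed = 9), 3)
  expect_identical(rr_a$recording$signal, rr_b$recording$signal)
})

test_that("recording CSV + trigger JSON round-trip", {
  co <- generate_cohort(1, 1, seed = 4, fs = 200)
  rr <- realize_recording(co, 1)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rec.csv")
  trg <- file.path(dir, "rec_triggers.json")
  write_recording_csv(rr$recording, csv)
  write_triggers_json(rr$recording, trg, truth = rr$truth)
  back <- read_recording_csv(csv, trg)
  expect_equal(back$signal, rr$recording$signal, tolerance = 1e-6)
  expect_equal(back$fs, 200)
  expect_equal(as.data.frame(back$epochs), as.data.frame(rr$recording$epochs))
})
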