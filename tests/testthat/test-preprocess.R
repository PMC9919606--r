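# centering, Butterworth design, zero-phase filtering, epoch segmentation

test_that("centering removes the mean and is idempotent", {
  expect_equal(ecg_center(rep(3.7, 10)), rep(0, 10))
  x <- c(1, 2, 3)
  expect_equal(ecg_center(x), c(-1, 0, 1))
  z <- rnorm(100)
  z <- z - mean(z)
  expect_equal(ecg_center(z), z)
  y <- rnorm(200)
  expect_equal(ecg_center(ecg_center(y)), ecg_center(y))
  expect_error(ecg_center(numeric(0)), "non-empty")
})

test_that("the 0.5-40 Hz degree-4 design reproduces the printed coefficients", {
  fl <- design_bandpass(0.5, 40, 1000, 4)
  expect_equal(round(fl$b, 4), c(0.0131, 0, -0.0261, 0, 0.0131))
  expect_equal(round(fl$a, 4), c(1, -3.6504, 5.0050, -3.0586, 0.7040))
})

test_that("designs are stable, pass mid-band and reject DC", {
  for (p in list(c(0.5, 40, 1000, 4), c(1, 30, 500, 4), c(0.5, 45, 250, 8))) {
    fl <- design_bandpass(p[1], p[2], p[3], p[4])
    expect_true(all(Mod(fl$poles) < 1))
    expect_equal(fl$a[1], 1)
    expect_length(fl$b, p[4] + 1)
    g_mid <- filter_gain(fl, sqrt(p[1] * p[2]))
    expect_gte(g_mid, 1 / sqrt(2))
    expect_lte(g_mid, 1 + 1e-9)
    expect_lt(filter_gain(fl, 0), 1e-6)
  }
  expect_error(design_bandpass(40, 0.5, 1000, 4), "low_hz")
  expect_error(design_bandpass(0.5, 600, 1000, 4), "low_hz")
  expect_error(design_bandpass(0.5, 40, 1000, 3), "even")
})

test_that("zero-phase filtering keeps symmetry and squares the magnitude", {
  fl <- design_bandpass(0.5, 40, 1000, 4)
  # symmetric pulse stays symmetric about its center
  n <- 4001
  x <- exp(-((seq_len(n) - 2001) / 40)^2)
  y <- apply_zero_phase(fl, x)
  expect_lt(max(abs(y - rev(y))), 1e-3) # edge transients of the 0.5 Hz HP
  expect_lt(max(abs(y - rev(y))[1001:3001]), 1e-4)
  expect_equal(which.max(y), 2001)

  t <- (0:29999) / 1000
  core <- 5000:25000
  y10 <- apply_zero_phase(fl, sin(2 * pi * 10 * t))
  expect_equal(max(abs(y10[core])), 1, tolerance = 0.02)
  ydrift <- apply_zero_phase(fl, sin(2 * pi * 0.05 * t))
  expect_lt(max(abs(ydrift[core])), 0.05)

  # filtering twice ~ |H|^4 on a mid-band sinusoid
  f0 <- 15
  g2 <- filter_gain(fl, f0)^2
  y1 <- apply_zero_phase(fl, sin(2 * pi * f0 * t))
  y2 <- apply_zero_phase(fl, y1)
  expect_equal(max(abs(y2[core])), g2^2, tolerance = 0.02)

  expect_error(apply_zero_phase(fl, rnorm(10)), "too short")
})

test_that("epoch segmentation follows the triggers exactly", {
  co <- generate_cohort(1, 1, seed = 2)
  rr <- realize_recording(co, 1)
  ep <- segment_epochs(rr$recording)
  expect_equal(ep$label, c("baseline", "warm1", "cpt", "warm2", "rest"))
  expect_equal(ep$end_sample[1] - ep$start_sample[1], 300000)
  expect_true(all(ep$start_sample[-1] == head(ep$end_sample, -1)))

  lay <- protocol_layout(cpt_s = 83)
  rec <- ecg_recording(numeric(max(lay$epochs$end_sample)), 1000, 1, 1,
                       lay$epochs[, c("label", "start_sample", "end_sample")])
  ep83 <- segment_epochs(rec)
  expect_equal(ep83$end_sample[3] - ep83$start_sample[3], 83000)

  bad <- rec
  bad$epochs <- bad$epochs[-2, ]
  expect_error(segment_epochs(bad), "five epochs")

  # filtering does not move epoch boundaries
  filt <- rec
  filt$signal <- apply_zero_phase(design_bandpass(0.5, 40, 1000, 4),
                                  rnorm(length(rec$signal)))
  expect_equal(segment_epochs(filt), ep83)
})
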