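# window geometry, the 21 features, baseline normalization, assembly

test_that("window counts follow floor((L - W)/step) + 1", {
  w300 <- make_windows(0, 300000, 1000)
  expect_equal(nrow(w300), 57)
  w120 <- make_windows(0, 120000, 1000)
  expect_equal(nrow(w120), 21)
  expect_equal(nrow(make_windows(0, 20000, 1000)), 1)
  expect_true(all(diff(w300$start) == 5000))
  expect_true(all(w300$end - w300$start == 20000))
  expect_true(all(w300$end <= 300000))
  expect_warning(w0 <- make_windows(0, 15000, 1000), "shorter")
  expect_equal(nrow(w0), 0)
  expect_error(make_windows(0, 100, 1000, overlap = 1), "overlap")
})

# independent brute-force re-count of the 21 features over a window
oracle_features <- function(fid, start, end, signal) {
  out <- list()
  for (wv in c("P", "R", "S", "T")) {
    pks <- c()
    for (i in seq_len(nrow(fid))) {
      p <- fid[[paste0(wv, "_peak")]][i]
      if (p >= start && p < end) pks <- c(pks, p)
    }
    out[[paste0(wv, "_peaks")]] <- length(pks)
    amps <- c()
    for (p in pks) amps <- c(amps, signal[p + 1])
    out[[paste0(wv, "_amplitude")]] <- if (length(amps)) mean(amps) else NA_real_
    ds <- c()
    if (length(pks) >= 2)
      for (i in 2:length(pks)) ds <- c(ds, pks[i] - pks[i - 1])
    out[[paste0(wv, "_distance")]] <- if (length(ds)) mean(ds) else NA_real_
  }
  for (wv in c("P", "R", "T")) {
    ons <- offs <- dists <- c()
    for (i in seq_len(nrow(fid))) {
      on <- fid[[paste0(wv, "_onset")]][i]
      off <- fid[[paste0(wv, "_offset")]][i]
      if (on >= start && on < end) ons <- c(ons, signal[on + 1])
      if (off >= start && off < end) offs <- c(offs, signal[off + 1])
      if (on >= start && on < end && off >= start && off < end)
        dists <- c(dists, off - on)
    }
    out[[paste0(wv, "_onsetamp")]] <- if (length(ons)) mean(ons) else NA_real_
    out[[paste0(wv, "_offsetamp")]] <- if (length(offs)) mean(offs) else NA_real_
    out[[paste0(wv, "_onoffdist")]] <- if (length(dists)) mean(dists) else NA_real_
  }
  out
}

test_that("extract_features agrees with the brute-force oracle", {
  st <- clean_train_60()
  fid <- st$truth$fiducials
  for (start in c(0, 37000, 299000)) {
    got <- extract_features(fid, start, start + 20000, st$signal)
    want <- oracle_features(fid, start, start + 20000, st$signal)
    for (f in pain_feature_names())
      expect_equal(got[[f]], want[[f]], label = sprintf("%s @ %d", f, start))
  }
})

test_that("clean 60 bpm windows carry the expected counts and distances", {
  st <- clean_train_60()
  fid <- st$truth$fiducials
  row <- extract_features(fid, 1000, 21000, st$signal)
  expect_equal(row$R_peaks, 20)
  expect_equal(row$R_distance, 1000)
  expect_equal(row$P_peaks, row$R_peaks)
  expect_equal(row$S_peaks, row$R_peaks)
  expect_equal(row$T_peaks, row$R_peaks)
  expect_false(row$incomplete)
  # all R amplitudes identical -> mean equals that value
  amp <- st$signal[fid$R_peak[1] + 1]
  expect_equal(row$R_amplitude, amp)
})

test_that("baseline normalization gives unit baseline means and recovers effects", {
  st <- clean_train_60()
  eff <- synth_beat_train(beat_model(hr_bpm = 60, rr_jitter = 0),
                          protocol_layout(cpt_s = 120),
                          effect_spec(hr_factor = 1, s_amp_factor = 0.7,
                                      t_amp_factor = 1, r_amp_factor = 1,
                                      t_offset_shift = 0), seed = 1)
  tab <- build_feature_table(eff$truth$fiducials, eff$signal,
                             eff$truth$epochs, 1000, 1, 1)
  norm <- normalize_by_baseline(tab)
  base <- norm$table[norm$table$epoch == "baseline", pain_feature_names()]
  expect_equal(unname(colMeans(base)), rep(1, 21))
  cpt <- norm$table[norm$table$epoch == "cpt", ]
  expect_equal(mean(cpt$S_amplitude), 0.7, tolerance = 0.05)

  # scale equivariance: amplitudes in c*signal normalize to the same values
  tab2 <- build_feature_table(eff$truth$fiducials, 3.5 * eff$signal,
                              eff$truth$epochs, 1000, 1, 1)
  norm2 <- normalize_by_baseline(tab2)
  amp_feats <- grep("amplitude|amp$", pain_feature_names(), value = TRUE)
  expect_equal(norm2$table[, amp_feats], norm$table[, amp_feats],
               tolerance = 1e-12)

  # no baseline windows -> contract violation
  no_base <- tab[tab$epoch != "baseline", ]
  expect_error(normalize_by_baseline(no_base), "baseline")
})

test_that("identity effect + zero noise gives identical class-conditional features", {
  st <- clean_train_60() # identity effect, jitter 0, no noise
  tab <- build_feature_table(st$truth$fiducials, st$signal, st$truth$epochs,
                             1000, 1, 1)
  feats <- pain_feature_names()
  base <- tab[tab$epoch == "baseline", feats]
  cpt <- tab[tab$epoch == "cpt", feats]
  # with a 1 s metronomic RR and 5 s window steps every window sees the same
  # beat pattern, so the distributions collapse to a single identical row
  expect_equal(unique(round(cpt, 10)), unique(round(base, 10)),
               ignore_attr = TRUE)
})

test_that("assemble_dataset labels cpt=1 / baseline=0 and drops incomplete rows", {
  st <- clean_train_60()
  tab <- build_feature_table(st$truth$fiducials, st$signal, st$truth$epochs,
                             1000, 7, 2)
  norm <- normalize_by_baseline(tab)
  ds <- suppressMessages(assemble_dataset(norm$table))
  expect_setequal(unique(ds$epoch), c("baseline", "cpt"))
  expect_equal(unique(ds$label[ds$epoch == "cpt"]), 1L)
  expect_equal(unique(ds$label[ds$epoch == "baseline"]), 0L)
  # full 120 s CPT: 57 baseline + 21 cpt rows per participant-session
  expect_equal(sum(ds$epoch == "baseline"), 57)
  expect_equal(sum(ds$epoch == "cpt"), 21)

  all5 <- suppressMessages(assemble_dataset(norm$table,
                                            epochs = unique(norm$table$epoch)))
  expect_true(all(is.na(all5$label[!all5$epoch %in% c("baseline", "cpt")])))

  only_base <- norm$table[norm$table$epoch == "baseline", ]
  expect_error(suppressMessages(assemble_dataset(only_base)), "both classes")
})
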