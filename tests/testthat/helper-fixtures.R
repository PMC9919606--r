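# Shared fixtures, built lazily and cached for the session so expensive
# synthetic cohorts are only processed once across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# clean metronomic 60 bpm recording over the full protocol, no noise
clean_train_60 <- function() {
  cached("clean60", {
    bm <- beat_model(hr_bpm = 60, rr_jitter = 0)
    synth_beat_train(bm, protocol_layout(cpt_s = 120), identity_effect(),
                     seed = 1)
  })
}

# its band-pass filtered signal and delineation (ground-truth convention)
clean_delineation_60 <- function() {
  cached("clean60_fid", {
    st <- clean_train_60()
    fl <- design_bandpass(0.5, 40, 1000, 4)
    filt <- apply_zero_phase(fl, ecg_center(st$signal))
    r <- detect_r_peaks(filt, 1000)
    fid <- delineate_waves(filt, r, 1000, onoff_frac = 0.05)
    list(signal = filt, r = r, fid = fid, truth = st$truth)
  })
}

# small default-effect cohort table (2 participants x 2 sessions)
small_cohort_table <- function() {
  cached("small_table", {
    co <- generate_cohort(n_participants = 2, n_sessions = 2, seed = 42)
    cohort_dataset(co)
  })
}

# full-protocol 36 x 2 cohort, processed once: detection scores against
# ground truth, ordering-invariant check, and the assembled feature table
full_cohort_results <- function(seed = 1) {
  cached(paste0("cohort36_", seed), {
    co <- generate_cohort(n_participants = 36, n_sessions = 2, seed = seed)
    fl <- design_bandpass(0.5, 40, 1000, 4)
    ord <- c("P_onset", "P_peak", "P_offset", "R_onset", "R_peak", "S_peak",
             "T_onset", "T_peak", "T_offset")
    n_true <- n_det <- n_match <- 0
    order_ok <- TRUE
    parts <- vector("list", length(co))
    t0 <- Sys.time()
    for (i in seq_len(length(co))) {
      rr <- realize_recording(co, i)
      filt <- apply_zero_phase(fl, ecg_center(rr$recording$signal))
      r <- detect_r_peaks(filt, 1000)
      sc <- score_r_peaks(r, rr$truth$fiducials$R_peak, 1000, tol_s = 0.010)
      n_true <- n_true + sc$n_true
      n_det <- n_det + sc$n_detected
      n_match <- n_match + sc$matched
      fid <- delineate_waves(filt, r, 1000)
      order_ok <- order_ok &&
        all(apply(fid[, ord], 1, function(v) all(diff(v) > 0))) &&
        all(fid$R_offset > fid$S_peak & fid$R_offset <= fid$T_onset)
      parts[[i]] <- build_feature_table(fid, filt,
                                        segment_epochs(rr$recording), 1000,
                                        rr$recording$participant,
                                        rr$recording$session)
    }
    table <- suppressMessages(
      assemble_dataset(normalize_by_baseline(do.call(rbind, parts))$table))
    list(table = table,
         sensitivity = n_match / n_true,
         false_positive_rate = (n_det - n_match) / n_det,
         order_ok = order_ok,
         pipeline_secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  })
}

# session-independent balanced accuracy of one family on a small cohort
small_cohort_balacc <- function(seed, effect, family = "random_forest",
                                n_participants = 4) {
  co <- generate_cohort(n_participants = n_participants, n_sessions = 2,
                        effect = effect, seed = seed)
  tab <- cohort_dataset(co)
  res <- run_experiment(tab, "session_independent",
                        roster = list(classifier_spec(family)), seed = seed)
  res$summary$value[res$summary$metric == "balanced_accuracy"]
}

# two separable Gaussian blobs in 2 features, labeled 0/1
blob_rows <- function(n = 60, gap = 4, seed = 99, extra_noise_feats = 0) {
  set.seed(seed)
  n2 <- n / 2
  X <- rbind(cbind(rnorm(n2), rnorm(n2)),
             cbind(rnorm(n2) + gap, rnorm(n2) + gap))
  d <- data.frame(f1 = X[, 1], f2 = X[, 2])
  if (extra_noise_feats > 0)
    for (j in seq_len(extra_noise_feats))
      d[[paste0("noise", j)]] <- rnorm(n)
  d$label <- rep(c(0L, 1L), each = n2)
  d
}

blob_feats <- function(rows) setdiff(names(rows), "label")
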