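# Synthetic protocol-structured ECG cohorts with analytic ground truth.
#
# Each heartbeat is a sum of five Gaussian wave components (P, Q, R, S, T),
# the classic phenomenological beat model: every fiducial then has a closed
# form, so the generator can emit exact ground truth alongside the signal.
# A cold-pressor ("CPT") epoch modulates heart rate and the S/T/R wave
# amplitudes, emulating a sympathetic pain response concentrated in the
# morphological features that downstream models are expected to pick up.

# fraction of a wave's peak amplitude at which its ground-truth onset and
# offset are defined; a Gaussian of width sigma crosses it at
# sigma * sqrt(2 * log(1/frac)) from the center
GT_ONOFF_FRACTION <- 0.05

onoff_halfwidth <- function(width, frac = GT_ONOFF_FRACTION) {
  width * sqrt(2 * log(1 / frac))
}

#' Beat morphology model
#'
#' Describes one heartbeat as five Gaussian components plus a heart rate and
#' a multiplicative RR-interval jitter. Default amplitudes, widths (Gaussian
#' sigma, seconds) and center offsets relative to the R peak are typical
#' lead-I adult values in millivolts.
#'
#' @param hr_bpm heart rate in beats per minute, in [30, 200].
#' @param rr_jitter standard deviation of the multiplicative (log-normal)
#'   RR-interval noise; 0 gives a metronomic rhythm.
#' @param waves data.frame with columns `wave` ("P","Q","R","S","T"), `amp`
#'   (mV), `width` (s), `center` (s, offset from the R peak). Centers must be
#'   strictly increasing in the order P < Q < R < S < T.
#' @return an object of class `beat_model`.
#' @export
beat_model <- function(hr_bpm = 70, rr_jitter = 0.03, waves = default_waves()) {
  assert_scalar_num(hr_bpm, "hr_bpm", 30, 200)
  assert_scalar_num(rr_jitter, "rr_jitter", 0)
  stopifnot(is.data.frame(waves),
            all(c("wave", "amp", "width", "center") %in% names(waves)))
  waves <- waves[match(c("P", "Q", "R", "S", "T"), waves$wave), ]
  if (anyNA(waves$wave)) stop_input("waves must contain P, Q, R, S and T rows")
  if (any(waves$width <= 0)) stop_input("wave widths must be positive")
  if (waves$amp[waves$wave == "R"] <= 0) stop_input("R amplitude must be positive")
  if (any(diff(waves$center) <= 0))
    stop_input("wave centers must be strictly ordered P < Q < R < S < T")
  structure(list(hr_bpm = hr_bpm, rr_jitter = rr_jitter, waves = waves),
            class = "beat_model")
}

#' @rdname beat_model
#' @export
default_waves <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.10, 1.00, -0.25, 0.35),
    width  = c(0.025, 0.010, 0.012, 0.012, 0.050),
    center = c(-0.200, -0.035, 0.000, 0.035, 0.260)
  )
}

#' CPT-epoch effect specification
#'
#' Multiplicative modulation applied to beats whose R peak falls inside the
#' CPT epoch. The defaults are synthetic: they inject a plausible sympathetic
#' pain response into exactly the morphological targets the downstream
#' feature-importance analysis is meant to recover (S, T and R amplitudes,
#' heart rate, and the signal level at the T offset).
#'
#' @param hr_factor multiplicative heart-rate change (> 0).
#' @param s_amp_factor,t_amp_factor,r_amp_factor multiplicative wave-amplitude
#'   changes (> 0).
#' @param t_offset_shift additive level shift (mV) of a narrow bump centered
#'   at the ground-truth T offset.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(hr_factor = 1.25, s_amp_factor = 0.7,
                        t_amp_factor = 0.8, r_amp_factor = 0.9,
                        t_offset_shift = -0.05) {
  for (nm in c("hr_factor", "s_amp_factor", "t_amp_factor", "r_amp_factor"))
    assert_scalar_num(get(nm), nm, 0, strict_lower = TRUE)
  assert_scalar_num(t_offset_shift, "t_offset_shift")
  structure(list(hr_factor = hr_factor, s_amp_factor = s_amp_factor,
                 t_amp_factor = t_amp_factor, r_amp_factor = r_amp_factor,
                 t_offset_shift = t_offset_shift),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
identity_effect <- function() effect_spec(1, 1, 1, 1, 0)

#' Additive noise specification
#'
#' Three canonical ECG contaminations: sinusoidal baseline wander (respiratory
#' / electrode drift, below the analysis band), sinusoidal powerline pickup,
#' and white broadband noise.
#'
#' @param wander_amp,wander_hz baseline-wander amplitude (mV) and frequency
#'   (Hz, must stay below 0.5 Hz so the analysis band-pass can remove it).
#' @param powerline_amp,powerline_hz mains-interference amplitude (mV) and
#'   frequency (Hz).
#' @param broadband_sd standard deviation (mV) of white noise.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(wander_amp = 0.10, wander_hz = 0.25,
                       powerline_amp = 0.02, powerline_hz = 50,
                       broadband_sd = 0.02) {
  assert_scalar_num(wander_amp, "wander_amp", 0)
  assert_scalar_num(wander_hz, "wander_hz", 0, 0.5, strict_lower = TRUE)
  if (wander_hz >= 0.5) stop_input("wander_hz must be below 0.5 Hz")
  assert_scalar_num(powerline_amp, "powerline_amp", 0)
  assert_scalar_num(powerline_hz, "powerline_hz", 0, strict_lower = TRUE)
  assert_scalar_num(broadband_sd, "broadband_sd", 0)
  structure(list(wander_amp = wander_amp, wander_hz = wander_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 broadband_sd = broadband_sd),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
zero_noise <- function() noise_spec(0, 0.25, 0, 50, 0)

#' Five-epoch protocol layout
#'
#' The recording protocol: a 5 min seated baseline, 2 min with the forearm in
#' warm water, the cold-pressor immersion (up to 2 min, participants may
#' withdraw early), another 2 min of warm water, and 5 min of rest.
#'
#' @param cpt_s CPT duration in seconds, in (0, 120].
#' @param fs sampling rate in Hz.
#' @return object of class `protocol_layout` with `epochs` (data.frame of
#'   `label`, `duration_s`, `start_sample`, `end_sample`; half-open 0-based
#'   sample intervals) and `fs`.
#' @export
protocol_layout <- function(cpt_s = 120, fs = 1000) {
  assert_scalar_num(cpt_s, "cpt_s", 0, 120, strict_lower = TRUE)
  assert_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  durations <- c(baseline = 300, warm1 = 120, cpt = cpt_s, warm2 = 120,
                 rest = 300)
  ends <- round(cumsum(durations) * fs)
  starts <- c(0, head(ends, -1))
  structure(list(
    epochs = data.frame(label = names(durations), duration_s = unname(durations),
                        start_sample = starts, end_sample = ends,
                        row.names = NULL),
    fs = fs
  ), class = "protocol_layout")
}

#' Synthesize one protocol-long beat train with ground truth
#'
#' Lays beats down across the whole protocol. RR intervals are
#' `60 / hr * exp(rnorm(1, 0, rr_jitter))`; the effect's heart-rate factor and
#' amplitude factors apply to exactly those beats whose R peak falls inside
#' the CPT epoch. Only beats whose complete support (including Gaussian
#' tails) fits in the record are synthesized, so signal and ground truth
#' always agree.
#'
#' Ground-truth onsets and offsets are placed where each wave component falls
#' to 5\% of its own peak amplitude; the ground-truth R onset and R offset are
#' the QRS-complex boundaries (Q-wave onset and S-wave offset).
#'
#' @param beat a [beat_model()].
#' @param layout a [protocol_layout()].
#' @param effect an [effect_spec()].
#' @param seed integer RNG seed.
#' @return list with `signal` (numeric, mV), `fs`, and `truth` — a list with
#'   `fiducials` (data.frame of 0-based sample indices, one row per beat,
#'   columns P_onset, P_peak, P_offset, R_onset, R_peak, R_offset, S_peak,
#'   T_onset, T_peak, T_offset) and `epochs` (the layout's epoch table).
#' @export
synth_beat_train <- function(beat, layout, effect = identity_effect(),
                             seed = 1L) {
  stopifnot(inherits(beat, "beat_model"), inherits(layout, "protocol_layout"),
            inherits(effect, "effect_spec"))
  fs <- layout$fs
  n <- max(layout$epochs$end_sample)
  duration <- n / fs
  w <- beat$waves
  wamp <- stats::setNames(w$amp, w$wave)
  wwid <- stats::setNames(w$width, w$wave)
  wcen <- stats::setNames(w$center, w$wave)

  cpt <- layout$epochs[layout$epochs$label == "cpt", ]
  cpt_t <- c(cpt$start_sample, cpt$end_sample) / fs

  # lead-in so the first beat's P wave (tails included) fits
  lead_in <- -(wcen[["P"]] - 4 * wwid[["P"]])
  tail_out <- wcen[["T"]] + 4 * wwid[["T"]]
  k_off <- onoff_halfwidth(1) # per-unit-width half-width at the 5% level

  set.seed(as.integer(seed))
  r_times <- numeric(0)
  t_cur <- lead_in + 0.1
  while (t_cur + tail_out < duration) {
    r_times <- c(r_times, t_cur)
    in_cpt <- t_cur >= cpt_t[1] && t_cur < cpt_t[2]
    hr <- beat$hr_bpm * if (in_cpt) effect$hr_factor else 1
    rr <- 60 / hr
    if (beat$rr_jitter > 0) rr <- rr * exp(rnorm(1, 0, beat$rr_jitter))
    t_cur <- t_cur + rr
  }
  nb <- length(r_times)
  if (nb == 0) stop_input("layout too short for a single beat")

  signal <- numeric(n)
  tt <- seq_len(n) / fs # time of sample index i-1 ... use (i-1)/fs instead
  tt <- (seq_len(n) - 1) / fs
  in_cpt <- r_times >= cpt_t[1] & r_times < cpt_t[2]
  amp_fac <- c(P = 1, Q = 1, R = 1, S = 1, T = 1)

  t_off_center <- wcen[["T"]] + onoff_halfwidth(wwid[["T"]])
  shift_sigma <- 0.012

  for (b in seq_len(nb)) {
    fac <- amp_fac
    if (in_cpt[b]) {
      fac[["R"]] <- effect$r_amp_factor
      fac[["S"]] <- effect$s_amp_factor
      fac[["T"]] <- effect$t_amp_factor
    }
    for (wv in c("P", "Q", "R", "S", "T")) {
      c0 <- r_times[b] + wcen[[wv]]
      sg <- wwid[[wv]]
      i1 <- max(1L, floor((c0 - 4 * sg) * fs) + 1L)
      i2 <- min(n, ceiling((c0 + 4 * sg) * fs) + 1L)
      idx <- i1:i2
      signal[idx] <- signal[idx] +
        wamp[[wv]] * fac[[wv]] * exp(-((tt[idx] - c0)^2) / (2 * sg^2))
    }
    if (in_cpt[b] && effect$t_offset_shift != 0) {
      c0 <- r_times[b] + t_off_center
      i1 <- max(1L, floor((c0 - 4 * shift_sigma) * fs) + 1L)
      i2 <- min(n, ceiling((c0 + 4 * shift_sigma) * fs) + 1L)
      idx <- i1:i2
      signal[idx] <- signal[idx] +
        effect$t_offset_shift * exp(-((tt[idx] - c0)^2) / (2 * shift_sigma^2))
    }
  }

  samp <- function(t) as.integer(round(t * fs)) # 0-based sample index
  fid <- data.frame(
    P_onset  = samp(r_times + wcen[["P"]] - onoff_halfwidth(wwid[["P"]])),
    P_peak   = samp(r_times + wcen[["P"]]),
    P_offset = samp(r_times + wcen[["P"]] + onoff_halfwidth(wwid[["P"]])),
    R_onset  = samp(r_times + wcen[["Q"]] - onoff_halfwidth(wwid[["Q"]])),
    R_peak   = samp(r_times),
    R_offset = samp(r_times + wcen[["S"]] + onoff_halfwidth(wwid[["S"]])),
    S_peak   = samp(r_times + wcen[["S"]]),
    T_onset  = samp(r_times + wcen[["T"]] - onoff_halfwidth(wwid[["T"]])),
    T_peak   = samp(r_times + wcen[["T"]]),
    T_offset = samp(r_times + wcen[["T"]] + onoff_halfwidth(wwid[["T"]]))
  )
  keep <- fid$P_onset >= 0 & fid$T_offset < n
  fid <- fid[keep, , drop = FALSE]
  rownames(fid) <- NULL

  list(signal = signal, fs = fs,
       truth = list(fiducials = fid,
                    epochs = layout$epochs[, c("label", "start_sample",
                                               "end_sample")]))
}

#' Add baseline wander, powerline interference and broadband noise
#'
#' @param signal numeric vector (mV).
#' @param noise a [noise_spec()].
#' @param seed integer RNG seed (controls sinusoid phases and white noise).
#' @param fs sampling rate (Hz).
#' @return noisy signal, same length.
#' @export
add_noise <- function(signal, noise, seed = 1L, fs = 1000) {
  stopifnot(inherits(noise, "noise_spec"))
  if (length(signal) == 0) stop_input("signal must be non-empty")
  set.seed(as.integer(seed))
  tt <- (seq_along(signal) - 1) / fs
  ph <- runif(2, 0, 2 * pi)
  out <- signal
  if (noise$wander_amp > 0)
    out <- out + noise$wander_amp * sin(2 * pi * noise$wander_hz * tt + ph[1])
  if (noise$powerline_amp > 0)
    out <- out + noise$powerline_amp * sin(2 * pi * noise$powerline_hz * tt + ph[2])
  if (noise$broadband_sd > 0)
    out <- out + rnorm(length(signal), 0, noise$broadband_sd)
  out
}

#' Single-channel ECG recording container
#'
#' @param signal numeric samples in mV.
#' @param fs sampling rate (Hz).
#' @param participant,session identifiers; session 1 is the fear-context CPT
#'   visit and session 2 the neutral-context visit.
#' @param epochs data.frame with `label`, `start_sample`, `end_sample`
#'   (half-open, 0-based) trigger annotations.
#' @return object of class `ecg_recording`.
#' @export
ecg_recording <- function(signal, fs, participant, session, epochs) {
  assert_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  stopifnot(is.numeric(signal), is.data.frame(epochs),
            all(c("label", "start_sample", "end_sample") %in% names(epochs)))
  if (any(epochs$end_sample > length(signal)))
    stop_input("trigger epochs extend beyond the signal")
  if (any(epochs$start_sample >= epochs$end_sample))
    stop_input("trigger epochs must be non-empty half-open intervals")
  structure(list(signal = signal, fs = fs, participant = participant,
                 session = session, epochs = epochs),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> participant %s, session %s: %d samples @ %g Hz (%.1f s), %d epochs\n",
              x$participant, x$session, length(x$signal), x$fs,
              length(x$signal) / x$fs, nrow(x$epochs)))
  invisible(x)
}

#' Generate a protocol-structured synthetic cohort
#'
#' Draws one beat morphology per participant (kept across sessions, as a real
#' person's ECG would be) and one CPT duration and noise realization per
#' session. Participant-level variation: heart rate is normal around the base
#' model's rate (sd 7 bpm, clipped to [45, 100]); wave amplitudes and widths
#' get independent log-normal factors (sd 0.10 and 0.05). CPT durations are
#' uniform on [60, 120] s, reflecting that most participants endured over a
#' minute but not all completed the two-minute limit.
#'
#' The returned cohort is lazy: recordings are realized on demand by
#' [realize_recording()] so a full 36 x 2 cohort does not need to live in
#' memory at once.
#'
#' @param n_participants,n_sessions cohort dimensions.
#' @param beat base [beat_model()] around which participants vary.
#' @param effect an [effect_spec()] applied in every CPT epoch.
#' @param noise a [noise_spec()].
#' @param seed integer cohort seed; all variation derives from it.
#' @param fs sampling rate (Hz).
#' @param cpt_range range (s) of per-session CPT durations.
#' @return object of class `ecg_cohort`; essentially a manifest. Use
#'   `length()`, [cohort_index()] and [realize_recording()].
#' @export
generate_cohort <- function(n_participants = 36, n_sessions = 2,
                            beat = beat_model(), effect = effect_spec(),
                            noise = noise_spec(), seed = 1L, fs = 1000,
                            cpt_range = c(60, 120)) {
  if (n_participants < 1) stop_input("empty cohort: n_participants must be >= 1")
  if (n_sessions < 1) stop_input("n_sessions must be >= 1")
  participants <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(derive_seed(seed, "participant", p))
    hr <- min(100, max(45, rnorm(1, beat$hr_bpm, 7)))
    w <- beat$waves
    w$amp <- w$amp * exp(rnorm(5, 0, 0.10))
    w$width <- w$width * exp(rnorm(5, 0, 0.05))
    participants[[p]] <- beat_model(hr_bpm = hr, rr_jitter = beat$rr_jitter,
                                    waves = w)
  }
  sessions <- expand.grid(participant = seq_len(n_participants),
                          session = seq_len(n_sessions))
  sessions <- sessions[order(sessions$participant, sessions$session), ]
  rownames(sessions) <- NULL
  sessions$cpt_s <- vapply(seq_len(nrow(sessions)), function(i) {
    set.seed(derive_seed(seed, "cpt", sessions$participant[i], sessions$session[i]))
    runif(1, cpt_range[1], cpt_range[2])
  }, numeric(1))
  structure(list(participants = participants, sessions = sessions,
                 effect = effect, noise = noise, seed = seed, fs = fs),
            class = "ecg_cohort")
}

#' @export
length.ecg_cohort <- function(x) nrow(x$sessions)

#' @rdname generate_cohort
#' @param cohort an `ecg_cohort`.
#' @export
cohort_index <- function(cohort) cohort$sessions

#' Realize one recording of a lazy cohort
#'
#' @param cohort an `ecg_cohort` from [generate_cohort()].
#' @param i recording index in `1:length(cohort)`.
#' @return list with `recording` (an [ecg_recording()]) and `truth` (ground
#'   truth as in [synth_beat_train()]).
#' @export
realize_recording <- function(cohort, i) {
  stopifnot(inherits(cohort, "ecg_cohort"), i >= 1, i <= length(cohort))
  row <- cohort$sessions[i, ]
  beat <- cohort$participants[[row$participant]]
  layout <- protocol_layout(cpt_s = row$cpt_s, fs = cohort$fs)
  s_beat <- derive_seed(cohort$seed, "beats", row$participant, row$session)
  s_noise <- derive_seed(cohort$seed, "noise", row$participant, row$session)
  clean <- synth_beat_train(beat, layout, cohort$effect, seed = s_beat)
  noisy <- add_noise(clean$signal, cohort$noise, seed = s_noise, fs = cohort$fs)
  rec <- ecg_recording(noisy, cohort$fs, row$participant, row$session,
                       layout$epochs[, c("label", "start_sample", "end_sample")])
  list(recording = rec, truth = clean$truth)
}

# ---- plain-text I/O ---------------------------------------------------------

#' Write / read a recording as two-column CSV with a `# fs=` header
#'
#' @param rec an [ecg_recording()].
#' @param path output path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g participant=%s session=%s", rec$fs,
                     rec$participant, rec$session), con)
  writeLines("time_s,amplitude_mV", con)
  tt <- (seq_along(rec$signal) - 1) / rec$fs
  writeLines(paste(format(tt, trim = TRUE, scientific = FALSE),
                   format(rec$signal, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param triggers_path path of the trigger JSON written by
#'   [write_triggers_json()]; required to reconstruct the epoch map.
#' @export
read_recording_csv <- function(path, triggers_path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("fs=([0-9.]+) participant=([^ ]+) session=([^ ]+)", header))[[1]]
  if (length(m) != 4) stop_input("missing `# fs=` header in %s", path)
  dat <- read.csv(path, comment.char = "#")
  trg <- jsonlite::read_json(triggers_path, simplifyVector = TRUE)
  ecg_recording(dat$amplitude_mV, as.numeric(m[2]), m[3], as.integer(m[4]),
                as.data.frame(trg$epochs))
}

#' Write trigger annotations (and optional ground truth) as JSON
#'
#' @param rec an [ecg_recording()].
#' @param path output path.
#' @param truth optional ground truth from [synth_beat_train()].
#' @export
write_triggers_json <- function(rec, path, truth = NULL) {
  obj <- list(participant = rec$participant, session = rec$session,
              epochs = rec$epochs)
  if (!is.null(truth)) obj$fiducials <- truth$fiducials
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
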