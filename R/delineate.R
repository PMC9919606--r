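# R-peak detection and P/QRS/T delineation.
#
# The QRS detector is a Pan-Tompkins style chain: differentiate, square,
# moving-window integrate (150 ms), then an adaptive signal/noise threshold
# with a 200 ms refractory period; each detection is refined to the local
# maximum of the band-passed signal. Delineation then searches bounded
# physiological windows around each R peak for the P and T extrema and the
# S trough, and places onsets/offsets where the signal falls to a fraction
# of the local wave prominence.

#' Detect R peaks in a band-passed ECG
#'
#' @param signal band-passed ECG (mV).
#' @param fs sampling rate (Hz).
#' @param refractory_s minimum distance between peaks (s).
#' @return integer vector of 0-based R-peak sample indices (possibly empty,
#'   with a warning, when no QRS-like activity is found).
#' @export
detect_r_peaks <- function(signal, fs, refractory_s = 0.2) {
  assert_scalar_num(fs, "fs", 0, strict_lower = TRUE)
  n <- length(signal)
  if (n < 2 * fs) stop_input("signal shorter than 2 s")

  d <- c(diff(signal), 0)
  sq <- d * d
  win <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  mwi[is.na(mwi)] <- 0

  if (max(mwi) <= 0) {
    warning("no QRS-like activity found")
    return(integer(0))
  }

  # candidate peaks of the integrated energy, >= refractory apart
  refr <- round(refractory_s * fs)
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0.01 * max(mwi)]
  if (length(cand) == 0) {
    warning("no QRS-like activity found")
    return(integer(0))
  }

  # adaptive signal / noise levels (Pan-Tompkins running estimates)
  spki <- max(mwi[seq_len(min(n, 2 * fs))])
  npki <- mean(mwi[seq_len(min(n, 2 * fs))])
  accepted <- integer(0)
  for (c0 in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[c0] >= thr) {
      accepted <- c(accepted, c0)
      spki <- 0.125 * mwi[c0] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[c0] + 0.875 * npki
    }
  }
  if (length(accepted) == 0) {
    warning("no QRS-like activity found")
    return(integer(0))
  }

  # refine to the maximum of the band-passed signal near each detection
  half <- as.integer(round(0.10 * fs))
  peaks <- vapply(as.integer(accepted), function(c0) {
    i1 <- max(1L, c0 - half)
    i2 <- min(as.integer(n), c0 + half)
    i1 + which.max(signal[i1:i2]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))

  # enforce refractory on the refined locations, keeping the taller peak
  if (length(peaks) > 1) {
    keep <- logical(length(peaks))
    last <- -Inf
    last_i <- 0L
    for (i in seq_along(peaks)) {
      if (peaks[i] - last >= refr) {
        keep[i] <- TRUE
        last <- peaks[i]
        last_i <- i
      } else if (signal[peaks[i]] > signal[peaks[last_i]]) {
        keep[last_i] <- FALSE
        keep[i] <- TRUE
        last <- peaks[i]
        last_i <- i
      }
    }
    peaks <- peaks[keep]
  }
  as.integer(peaks - 1L) # 0-based
}

# walk from `from` in direction `dir` until the signal crosses `level`
# (sgn = +1 for positive waves, -1 for troughs). When the level is never
# reached before `limit` — waves overlapping at high heart rates — fall back
# to the extremum of the walking span, the standard turning-point surrogate
# for an onset/offset. Returns a 0-based index, or NA on an empty span.
walk_to_level <- function(signal, from, dir, limit, sgn, level) {
  i <- from
  while (i != limit && sgn * (signal[i] - level) > 0) i <- i + dir
  if (sgn * (signal[i] - level) > 0) {
    span <- seq(from + dir, limit, by = dir)
    if (length(span) == 0) return(NA_integer_)
    i <- span[which.min(sgn * signal[span])]
  }
  i - 1L
}

#' Delineate P, QRS and T waves around detected R peaks
#'
#' For each R peak the P peak is sought in `p_window` before R, the S trough
#' in `s_window` after R, the Q trough between the P window and R, and the T
#' peak in `t_window` after R. Onsets and offsets are the samples where the
#' signal first falls below `onoff_frac` of the wave's prominence (its
#' unsigned peak amplitude) when walking away from the peak. The R onset and
#' R offset are the QRS boundaries, i.e. the Q-wave onset and the S-wave
#' offset. Beats for which any fiducial cannot be located are dropped and
#' counted in `n_dropped`.
#'
#' @param signal band-passed ECG (mV), positive R polarity.
#' @param r_peaks 0-based R-peak indices from [detect_r_peaks()].
#' @param fs sampling rate (Hz).
#' @param onoff_frac onset/offset threshold as a fraction of wave prominence.
#'   The default 0.10 is conservative for noisy data; set it to 0.05 to match
#'   the synthetic ground-truth convention.
#' @param p_window,s_window,t_window search windows (s) relative to R.
#' @return object of class `fiducial_set`: data.frame of 0-based indices with
#'   columns P_onset, P_peak, P_offset, R_onset, R_peak, R_offset, S_peak,
#'   T_onset, T_peak, T_offset; attributes `fs` and `n_dropped`.
#' @export
delineate_waves <- function(signal, r_peaks, fs, onoff_frac = 0.10,
                            p_window = c(-0.25, -0.06),
                            s_window = c(0, 0.12),
                            t_window = c(0.12, 0.45)) {
  if (length(r_peaks) < 2) stop_input("delineation requires at least 2 R peaks")
  n <- length(signal)
  r1 <- r_peaks + 1L # 1-based

  if (median(signal[r1]) < 0)
    stop_input("R peaks have negative polarity; invert the signal first")

  rows <- vector("list", length(r1))
  dropped <- 0L
  for (k in seq_along(r1)) {
    r <- r1[k]
    out <- tryCatch({
      # bounded search windows, clipped to neighbours and record edges
      p1 <- max(1L, r + round(p_window[1] * fs))
      p2 <- max(1L, r + round(p_window[2] * fs))
      if (k > 1) p1 <- max(p1, r1[k - 1] + round(0.15 * fs))
      s1 <- r + round(s_window[1] * fs)
      s2 <- min(n, r + round(s_window[2] * fs))
      t1 <- min(n, r + round(t_window[1] * fs))
      t2 <- min(n, r + round(t_window[2] * fs))
      if (k < length(r1)) t2 <- min(t2, r1[k + 1] - round(0.15 * fs))
      if (p2 <= p1 || s2 <= s1 || t2 <= t1) stop("window")

      p_pk <- p1 + which.max(signal[p1:p2]) - 1L
      s_pk <- s1 + which.min(signal[s1:s2]) - 1L
      t_pk <- t1 + which.max(signal[t1:t2]) - 1L
      q1 <- p2
      q_pk <- q1 + which.min(signal[q1:(r - 1L)]) - 1L

      lim_right <- if (k < length(r1)) r1[k + 1] - round(0.1 * fs) else n

      # local isoelectric reference: the PR segment between P offset and QRS
      # onset; prominences and crossing levels are measured from it because
      # the band-pass shifts the inter-beat baseline away from zero
      base <- median(signal[max(1L, r - round(0.13 * fs)):(r - round(0.07 * fs))])
      lv <- function(pk) base + onoff_frac * (signal[pk] - base)
      sg <- function(pk) if (signal[pk] >= base) 1 else -1

      p_on <- walk_to_level(signal, p_pk, -1L, max(1L, r - round(0.35 * fs)),
                            sg(p_pk), lv(p_pk))
      p_off <- walk_to_level(signal, p_pk, 1L, q_pk, sg(p_pk), lv(p_pk))
      r_on <- walk_to_level(signal, q_pk, -1L, p_pk, sg(q_pk), lv(q_pk))
      r_off <- walk_to_level(signal, s_pk, 1L, t1, sg(s_pk), lv(s_pk))
      t_on <- walk_to_level(signal, t_pk, -1L, s_pk, sg(t_pk), lv(t_pk))
      t_off <- walk_to_level(signal, t_pk, 1L,
                             min(n, r + round(0.60 * fs), lim_right),
                             sg(t_pk), lv(t_pk))
      vals <- c(P_onset = p_on, P_peak = p_pk - 1L, P_offset = p_off,
                R_onset = r_on, R_peak = r - 1L, R_offset = r_off,
                S_peak = s_pk - 1L, T_onset = t_on, T_peak = t_pk - 1L,
                T_offset = t_off)
      if (anyNA(vals)) stop("incomplete")
      # enforce the within-beat ordering contract; drop violating beats
      if (any(diff(vals[c("P_onset", "P_peak", "P_offset", "R_onset",
                          "R_peak", "S_peak", "T_onset", "T_peak",
                          "T_offset")]) <= 0)) stop("order")
      if (vals["R_offset"] <= vals["S_peak"] || vals["R_offset"] > vals["T_onset"])
        stop("order")
      vals
    }, error = function(e) NULL)
    if (is.null(out)) dropped <- dropped + 1L else rows[[k]] <- out
  }
  fid <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
  if (nrow(fid) == 0) stop_input("no complete beats could be delineated")
  structure(fid, fs = fs, n_dropped = dropped,
            class = c("fiducial_set", "data.frame"))
}

#' Score detected R peaks against ground truth
#'
#' Greedy one-to-one matching within a tolerance.
#'
#' @param detected,truth 0-based sample indices.
#' @param fs sampling rate (Hz).
#' @param tol_s matching tolerance (s).
#' @return list with `n_true`, `n_detected`, `matched`, `sensitivity`
#'   (matched / n_true) and `false_positive_rate` (unmatched detections /
#'   n_detected).
#' @export
score_r_peaks <- function(detected, truth, fs, tol_s = 0.010) {
  tol <- tol_s * fs
  matched <- 0L
  j <- 1L
  used <- logical(length(detected))
  for (t in truth) {
    hits <- which(!used & abs(detected - t) <= tol)
    if (length(hits) > 0) {
      used[hits[which.min(abs(detected[hits] - t))]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = length(truth), n_detected = length(detected),
       matched = matched,
       sensitivity = if (length(truth)) matched / length(truth) else NA_real_,
       false_positive_rate = if (length(detected))
         (length(detected) - sum(used)) / length(detected) else NA_real_)
}

#' Serialize / read a fiducial set as JSON
#'
#' The schema mirrors the generator's ground truth, so externally produced
#' fiducials (for example from another toolkit) can be imported and scored
#' identically.
#'
#' @param fid a `fiducial_set`.
#' @param path file path.
#' @export
write_fiducials_json <- function(fid, path) {
  jsonlite::write_json(list(fs = attr(fid, "fs"),
                            n_dropped = attr(fid, "n_dropped"),
                            fiducials = as.data.frame(fid)),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fiducials_json
#' @export
read_fiducials_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as.data.frame(obj$fiducials), fs = obj$fs,
            n_dropped = obj$n_dropped %||% 0L,
            class = c("fiducial_set", "data.frame"))
}
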