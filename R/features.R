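# Windowed morphological features and baseline-mean normalization.
#
# Twenty-one features per 20 s window (75% overlap): per-wave peak counts,
# mean peak amplitudes, mean consecutive-peak distances (in samples), mean
# onset/offset amplitudes and mean onset-to-offset distances. Every feature
# of every epoch is then divided by its mean over the baseline epoch of the
# same participant-session, so models see relative change from rest.

#' The 21 morphological feature names, in canonical column order
#' @export
pain_feature_names <- function() {
  c(paste0(c("P", "R", "S", "T"), "_peaks"),
    paste0(c("P", "R", "S", "T"), "_amplitude"),
    paste0(c("P", "R", "S", "T"), "_distance"),
    paste0(c("P", "R", "T"), "_onsetamp"),
    paste0(c("P", "R", "T"), "_offsetamp"),
    paste0(c("P", "R", "T"), "_onoffdist"))
}

#' Sliding-window intervals inside an epoch
#'
#' Windows of `window_s` seconds advance by `window_s * (1 - overlap)` (5 s at
#' the defaults); a trailing partial window is dropped, so an epoch of length
#' L seconds yields `floor((L - window_s) / step) + 1` windows.
#'
#' @param start_sample,end_sample half-open 0-based epoch bounds.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap in [0, 1).
#' @return data.frame `start`, `end` (half-open, 0-based sample indices);
#'   zero rows (with a warning) if the epoch is shorter than one window.
#' @export
make_windows <- function(start_sample, end_sample, fs, window_s = 20,
                         overlap = 0.75) {
  assert_scalar_num(window_s, "window_s", 0, strict_lower = TRUE)
  if (overlap < 0 || overlap >= 1) stop_input("overlap must be in [0, 1)")
  w <- round(window_s * fs)
  step <- round(window_s * (1 - overlap) * fs)
  len <- end_sample - start_sample
  if (len < w) {
    warning("epoch shorter than one window; no windows produced")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  nwin <- floor((len - w) / step) + 1
  starts <- start_sample + (seq_len(nwin) - 1) * step
  data.frame(start = starts, end = starts + w)
}

# means that return NA (not NaN) on empty input
mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Compute the 21 features for one window
#'
#' A fiducial belongs to the window when its sample index lies in
#' `[start, end)`. Distances use only consecutive same-type peaks that are
#' both in-window; `*_onoffdist` is the per-beat onset-to-offset duration
#' (wave width) averaged over beats whose onset and offset are both
#' in-window. Windows in which any feature is undefined (no events, or fewer
#' than two peaks for a distance) are flagged `incomplete`.
#'
#' @param fid a `fiducial_set` (or ground-truth fiducial data.frame).
#' @param start,end half-open 0-based window bounds.
#' @param signal the band-passed signal the fiducials index into.
#' @return one-row data.frame of the 21 features plus `incomplete`.
#' @export
extract_features <- function(fid, start, end, signal) {
  fid <- as.data.frame(fid)
  out <- list()
  for (wv in c("P", "R", "S", "T")) {
    pk <- fid[[paste0(wv, "_peak")]]
    pk <- pk[pk >= start & pk < end]
    out[[paste0(wv, "_peaks")]] <- length(pk)
    out[[paste0(wv, "_amplitude")]] <- mean_or_na(signal[pk + 1L])
    out[[paste0(wv, "_distance")]] <- if (length(pk) >= 2)
      mean(diff(pk)) else NA_real_
  }
  for (wv in c("P", "R", "T")) {
    on <- fid[[paste0(wv, "_onset")]]
    off <- fid[[paste0(wv, "_offset")]]
    on_in <- on[on >= start & on < end]
    off_in <- off[off >= start & off < end]
    both <- on >= start & on < end & off >= start & off < end
    out[[paste0(wv, "_onsetamp")]] <- mean_or_na(signal[on_in + 1L])
    out[[paste0(wv, "_offsetamp")]] <- mean_or_na(signal[off_in + 1L])
    out[[paste0(wv, "_onoffdist")]] <- mean_or_na(off[both] - on[both])
  }
  row <- as.data.frame(out)[, pain_feature_names()]
  row$incomplete <- anyNA(row)
  row
}

#' Build the windowed feature table for one recording
#'
#' @param fid fiducials for the recording (delineated or ground truth).
#' @param signal the band-passed signal.
#' @param epochs epoch map (label / start_sample / end_sample).
#' @param fs sampling rate (Hz).
#' @param participant,session identifiers copied into every row.
#' @param window_s,overlap window geometry, see [make_windows()].
#' @return data.frame: metadata columns (participant, session, epoch,
#'   window_start), the 21 features, and `incomplete`.
#' @export
build_feature_table <- function(fid, signal, epochs, fs, participant, session,
                                window_s = 20, overlap = 0.75) {
  out <- vector("list", nrow(epochs))
  for (e in seq_len(nrow(epochs))) {
    wins <- suppressWarnings(
      make_windows(epochs$start_sample[e], epochs$end_sample[e], fs,
                   window_s, overlap))
    if (nrow(wins) == 0) next
    rows <- lapply(seq_len(nrow(wins)), function(i)
      extract_features(fid, wins$start[i], wins$end[i], signal))
    rows <- do.call(rbind, rows)
    rows <- cbind(data.frame(participant = participant, session = session,
                             epoch = epochs$label[e],
                             window_start = wins$start),
                  rows)
    out[[e]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize features by the baseline-epoch mean
#'
#' For every participant-session, each of the 21 features is divided by its
#' mean over that participant-session's baseline windows (complete windows
#' only). The baseline rows themselves are normalized too, so their
#' per-feature mean is exactly 1.
#'
#' @param table a feature table from [build_feature_table()] (rows from any
#'   number of recordings).
#' @return list with `table` (normalized) and `reference` (data.frame of the
#'   baseline means per participant-session).
#' @export
normalize_by_baseline <- function(table) {
  feats <- pain_feature_names()
  stopifnot(all(feats %in% names(table)))
  key <- interaction(table$participant, table$session, drop = TRUE)
  refs <- vector("list", nlevels(key))
  for (k in seq_len(nlevels(key))) {
    sel <- key == levels(key)[k]
    base <- table[sel & table$epoch == "baseline" & !table$incomplete, feats,
                  drop = FALSE]
    if (nrow(base) == 0)
      stop_input("participant-session %s has no complete baseline window",
                 levels(key)[k])
    mu <- colMeans(base)
    bad <- feats[!is.finite(mu) | mu == 0]
    if (length(bad) > 0)
      stop_input("baseline mean is zero or non-finite for feature(s): %s",
                 paste(bad, collapse = ", "))
    table[sel, feats] <- sweep(table[sel, feats, drop = FALSE], 2, mu, "/")
    refs[[k]] <- cbind(data.frame(participant = table$participant[sel][1],
                                  session = table$session[sel][1]),
                       as.data.frame(as.list(mu)))
  }
  list(table = table, reference = do.call(rbind, refs))
}

#' Assemble the labeled baseline-vs-CPT dataset
#'
#' Restricts a normalized feature table to the epochs of interest, drops
#' incomplete rows (their count is reported via message), and attaches the
#' class label: CPT is the positive class (1), baseline the negative (0).
#'
#' @param table normalized feature table.
#' @param epochs epochs to keep; rows from other epochs are dropped. Epochs
#'   other than baseline/cpt, if requested, get label `NA`.
#' @return the labeled table with a `label` column.
#' @export
assemble_dataset <- function(table, epochs = c("baseline", "cpt")) {
  keep <- table$epoch %in% epochs
  table <- table[keep, , drop = FALSE]
  n_inc <- sum(table$incomplete)
  if (n_inc > 0) {
    message(sprintf("dropping %d incomplete window(s)", n_inc))
    table <- table[!table$incomplete, , drop = FALSE]
  }
  table$label <- ifelse(table$epoch == "cpt", 1L,
                        ifelse(table$epoch == "baseline", 0L, NA_integer_))
  lab <- table$label[!is.na(table$label)]
  if (!any(lab == 0) || !any(lab == 1))
    stop_input("dataset needs rows of both classes (baseline and cpt)")
  rownames(table) <- NULL
  table
}

#' Write / read a feature table as CSV
#' @param table a feature table.
#' @param path file path.
#' @export
write_feature_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
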