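# Centering, Butterworth band-pass design, zero-phase application, and
# protocol-epoch segmentation.
#
# The band-pass is designed from first principles (analog Butterworth
# prototype -> low-pass-to-band-pass transform -> bilinear transform with
# frequency prewarping), because the digital transfer function H(z) is the
# one fully printed computational artifact this pipeline must reproduce
# exactly. "Order 4" refers to the degree of H(z): an order-2 analog
# prototype becomes a degree-4 digital band-pass.

#' Remove the mean of a signal
#'
#' @param signal non-empty numeric vector.
#' @return signal minus its mean.
#' @export
ecg_center <- function(signal) {
  if (length(signal) == 0 || !is.numeric(signal))
    stop_input("signal must be a non-empty numeric vector")
  signal - mean(signal)
}

# polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0i) - c(0i, p * x)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Bilinear-transform design with frequency prewarping. `order` is the degree
#' of the resulting H(z) (numerator and denominator both of degree `order`);
#' it must be even, and the underlying analog low-pass prototype has order
#' `order / 2`.
#'
#' @param low_hz,high_hz pass-band edges, 0 < low < high < fs/2.
#' @param fs_hz sampling rate (Hz).
#' @param order degree of H(z); even.
#' @return object of class `filter_spec` with fields `b`, `a` (length
#'   `order + 1`, `a[1] == 1`), `low_hz`, `high_hz`, `fs_hz`, `order`.
#' @examples
#' fl <- design_bandpass(0.5, 40, 1000, 4)
#' round(fl$b, 4) # 0.0131 0 -0.0261 0 0.0131
#' @export
design_bandpass <- function(low_hz, high_hz, fs_hz, order = 4) {
  assert_scalar_num(low_hz, "low_hz", 0, strict_lower = TRUE)
  assert_scalar_num(high_hz, "high_hz", 0, strict_lower = TRUE)
  assert_scalar_num(fs_hz, "fs_hz", 0, strict_lower = TRUE)
  if (low_hz >= high_hz || high_hz >= fs_hz / 2)
    stop_input("need 0 < low_hz < high_hz < fs_hz/2")
  if (order %% 2 != 0 || order < 2)
    stop_input("order must be a positive even integer (degree of H(z))")
  np <- order / 2 # analog prototype order

  # Butterworth prototype poles on the unit left-half-plane circle
  k <- seq_len(np)
  p <- exp(1i * pi * (2 * k + np - 1) / (2 * np))

  # prewarped band edges and low-pass -> band-pass transform (zpk domain)
  fs2 <- 2 * fs_hz
  w1 <- fs2 * tan(pi * low_hz / fs_hz)
  w2 <- fs2 * tan(pi * high_hz / fs_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  ps <- p * bw / 2
  poles_a <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  zeros_a <- rep(0 + 0i, np)
  gain_a <- bw^np

  # bilinear transform; degree deficit of the numerator becomes zeros at z=-1
  poles_d <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_d <- c((fs2 + zeros_a) / (fs2 - zeros_a), rep(-1 + 0i, np))
  gain_d <- gain_a * Re(prod(fs2 - zeros_a) / prod(fs2 - poles_a))

  b <- Re(gain_d * poly_from_roots(zeros_d))
  a <- Re(poly_from_roots(poles_d))
  b <- b / a[1]
  a <- a / a[1]
  if (any(Mod(poles_d) >= 1)) stop_input("designed filter is unstable")
  structure(list(b = b, a = a, low_hz = low_hz, high_hz = high_hz,
                 fs_hz = fs_hz, order = order, poles = poles_d),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth band-pass %g-%g Hz @ %g Hz, degree %d\n",
              x$low_hz, x$high_hz, x$fs_hz, x$order))
  cat("  b:", paste(signif(x$b, 5), collapse = " "), "\n")
  cat("  a:", paste(signif(x$a, 5), collapse = " "), "\n")
  invisible(x)
}

#' Magnitude response of a filter at given frequencies
#'
#' @param spec a `filter_spec`.
#' @param f_hz frequencies (Hz).
#' @return |H(e^{j 2 pi f / fs})| at each frequency.
#' @export
filter_gain <- function(spec, f_hz) {
  z <- exp(-1i * 2 * pi * f_hz / spec$fs_hz)
  num <- sapply(seq_along(f_hz), function(i) sum(spec$b * z[i]^(seq_along(spec$b) - 1)))
  den <- sapply(seq_along(f_hz), function(i) sum(spec$a * z[i]^(seq_along(spec$a) - 1)))
  Mod(num / den)
}

#' Serialize a filter design to JSON (for run audit)
#' @param spec a `filter_spec`.
#' @param path output path.
#' @export
write_filter_json <- function(spec, path) {
  jsonlite::write_json(spec[c("b", "a", "low_hz", "high_hz", "fs_hz", "order")],
                       path, digits = NA)
  invisible(path)
}

#' Apply a filter forward and backward (zero net phase)
#'
#' The signal is reflect-padded (odd reflection about the end points) by
#' `3 * order` samples on each side, filtered, reversed, filtered again,
#' reversed, and cropped. The effective magnitude response is |H(z)|^2 and
#' the net phase is zero, so peaks are not displaced.
#'
#' @param spec a `filter_spec` from [design_bandpass()].
#' @param signal numeric vector; must be longer than `3 * order`.
#' @return filtered signal, same length as the input.
#' @export
apply_zero_phase <- function(spec, signal) {
  stopifnot(inherits(spec, "filter_spec"))
  npad <- 3L * spec$order
  n <- length(signal)
  if (n <= npad) stop_input("signal too short for zero-phase filtering (need > %d samples)", npad)
  pre <- 2 * signal[1] - signal[seq(npad + 1, 2)]
  post <- 2 * signal[n] - signal[seq(n - 1, n - npad)]
  x <- c(pre, signal, post)
  y <- .iir_filter(spec$b, spec$a, x)
  y <- rev(.iir_filter(spec$b, spec$a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Segment a recording into the five protocol epochs
#'
#' @param recording an [ecg_recording()] whose trigger annotations carry the
#'   five labels baseline, warm1, cpt, warm2, rest.
#' @return an `epoch_map`: data.frame `label`, `start_sample`, `end_sample`
#'   (half-open, 0-based), ordered and disjoint.
#' @export
segment_epochs <- function(recording) {
  stopifnot(inherits(recording, "ecg_recording"))
  ep <- recording$epochs
  want <- c("baseline", "warm1", "cpt", "warm2", "rest")
  if (!setequal(ep$label, want) || nrow(ep) != 5)
    stop_input("trigger annotations must contain exactly the five epochs: %s",
               paste(want, collapse = ", "))
  ep <- ep[match(want, ep$label), ]
  if (any(ep$start_sample[-1] < ep$end_sample[-5]))
    stop_input("trigger epochs overlap")
  if (any(ep$end_sample > length(recording$signal)))
    stop_input("trigger epochs extend beyond the signal")
  rownames(ep) <- NULL
  class(ep) <- c("epoch_map", "data.frame")
  ep
}

#' Center and band-pass filter a recording
#'
#' Convenience wrapper: centers the signal, applies the zero-phase band-pass,
#' and returns the recording with the filtered signal in place.
#'
#' @param recording an [ecg_recording()].
#' @param spec a `filter_spec`; defaults to the 0.5-40 Hz degree-4 design at
#'   the recording's sampling rate.
#' @return the filtered [ecg_recording()].
#' @export
preprocess_recording <- function(recording,
                                 spec = design_bandpass(0.5, 40, recording$fs, 4)) {
  recording$signal <- apply_zero_phase(spec, ecg_center(recording$signal))
  recording
}
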