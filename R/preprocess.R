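#' Remove the leading seconds of every trial
#'
#' Drops the first `trim_s` seconds from the time axis of each trial (used to
#' discard the pre-stimulus baseline, e.g. 3 s on 63-s trials leaving 60 s).
#'
#' @param rec an `eeg_recording`.
#' @param trim_s seconds to remove; `trim_s * fs` must be an integer strictly
#'   smaller than the trial length.
#' @return the trimmed `eeg_recording`.
#' @export
trim_lead <- function(rec, trim_s) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_trim <- trim_s * rec$fs
  if (abs(n_trim - round(n_trim)) > 1e-8) {
    stopf("trim_s * fs = %g is not an integer number of samples", n_trim)
  }
  n_trim <- as.integer(round(n_trim))
  n_time <- dim(rec$data)[4]
  if (n_trim >= n_time) stopf("cannot trim %g s from a %g s trial", trim_s, n_time / rec$fs)
  if (n_trim > 0) {
    rec$data <- rec$data[, , , (n_trim + 1):n_time, drop = FALSE]
  }
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters each channel with an order-`order` Butterworth band-pass applied
#' forward and backward (`signal::filtfilt`), so the output has no phase
#' distortion -- important because downstream channel-pair correlations are
#' phase-sensitive.
#'
#' @param x numeric matrix `channels x time` (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @return filtered matrix, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 4) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stopf("band (%g, %g) Hz invalid for fs = %g Hz (need 0 < low < high < fs/2)",
          low, high, fs)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  dimnames(out) <- dimnames(x)
  out
}

#' Decompose a recording into frequency bands
#'
#' Applies [bandpass_filter()] once per band to every trial and flattens the
#' subjects/trials axes to a single trial axis (subject-major order) with a
#' provenance table retained.
#'
#' @param rec an `eeg_recording`.
#' @param band_edges list of `c(low, high)` Hz pairs (default
#'   [default_bands()]).
#' @param order Butterworth order (default 4).
#' @return object of class `band_stack`: list with `data`
#'   (array `[trials_total, bands, channels, time]`), `fs`, `band_edges`,
#'   `labels` (length `trials_total`), and `provenance`
#'   (data.frame `subject`, `trial`).
#' @export
decompose_bands <- function(rec, band_edges = default_bands(), order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  validate_band_edges(band_edges, rec$fs)
  d <- dim(rec$data)
  n_flat <- d[1] * d[2]
  nb <- length(band_edges)
  out <- array(0, dim = c(n_flat, nb, d[3], d[4]))
  labels <- integer(n_flat)
  prov <- data.frame(subject = integer(n_flat), trial = integer(n_flat))
  filters <- lapply(band_edges, function(be) {
    signal::butter(order, c(be[1], be[2]) / (rec$fs / 2), type = "pass")
  })
  i <- 0L
  for (s in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      i <- i + 1L
      x <- array(rec$data[s, tr, , ], dim = d[3:4])  # robust to 1-channel data
      for (b in seq_len(nb)) {
        out[i, b, , ] <- t(apply(x, 1, function(row) signal::filtfilt(filters[[b]], row)))
      }
      labels[i] <- rec$labels[s, tr]
      prov$subject[i] <- s
      prov$trial[i] <- tr
    }
  }
  structure(list(
    data = out, fs = rec$fs, band_edges = band_edges,
    labels = labels, provenance = prov
  ), class = "band_stack")
}

#' Downsample a recording
#'
#' Resamples every channel to `target_fs` using polyphase FIR resampling
#' (`signal::resample`), which applies the anti-alias low-pass implicitly.
#' The output length is `ceiling(n * p / q)` where `p/q = target_fs/fs` in
#' lowest terms; for integer decimation ratios this equals `n * target_fs/fs`
#' exactly (512 Hz -> 128 Hz turns 63 s into 8064 samples).
#'
#' @param rec an `eeg_recording`.
#' @param target_fs new sampling rate in Hz, `<= fs`.
#' @return resampled `eeg_recording` with `fs = target_fs`.
#' @export
downsample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) stopf("upsampling (%g -> %g Hz) is not supported", rec$fs, target_fs)
  if (target_fs == rec$fs) return(rec)
  frac <- ratio_lowest_terms(target_fs, rec$fs)
  d <- dim(rec$data)
  new_len <- as.integer(ceiling(d[4] * frac[1] / frac[2]))
  out <- array(0, dim = c(d[1], d[2], d[3], new_len))
  for (s in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      for (ch in seq_len(d[3])) {
        out[s, tr, ch, ] <- signal::resample(rec$data[s, tr, ch, ], frac[1], frac[2])
      }
    }
  }
  rec$data <- out
  rec$fs <- target_fs
  rec
}

ratio_lowest_terms <- function(p, q) {
  # integerize rates like 128/512 or 128/200
  scale <- 1
  while (abs(p * scale - round(p * scale)) > 1e-9 ||
         abs(q * scale - round(q * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) stopf("cannot express %g/%g as an integer ratio", p, q)
  }
  pi_ <- round(p * scale); qi <- round(q * scale)
  g <- gcd_int(pi_, qi)
  c(pi_ / g, qi / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Number of sliding windows that fit in a trial
#'
#' Windows are aligned to the trial start with no padding of a trailing
#' partial window: starts are `0, step, 2*step, ...` while
#' `start + window <= duration`, giving
#' `floor((duration - window)/step) + 1` segments.
#'
#' @param duration_s trial duration (seconds).
#' @param window_s window length (seconds).
#' @param step_s step between window starts (seconds).
#' @return integer segment count.
#' @export
n_segments <- function(duration_s, window_s, step_s) {
  if (window_s > duration_s) stopf("window (%g s) longer than trial (%g s)", window_s, duration_s)
  if (step_s <= 0) stopf("step_s must be > 0")
  as.integer(floor((duration_s - window_s) / step_s + 1e-9) + 1)
}

#' Cut a band stack into overlapping windows
#'
#' Segments every trial of a [decompose_bands()] output with a sliding
#' window. Each segment inherits the label of its source trial, and
#' provenance records `(subject, trial, window_start_s)` per segment.
#'
#' @param stack a `band_stack`.
#' @param window_s window length in seconds.
#' @param step_s step between window starts in seconds (overlap =
#'   `window_s - step_s`).
#' @return object of class `segment_set`: list with `data`
#'   (array `[segments_total, bands, channels, window_samples]`), `fs`,
#'   `band_edges`, `labels`, `provenance`, `window_s`, `step_s`.
#' @export
segment_windows <- function(stack, window_s, step_s) {
  stopifnot(inherits(stack, "band_stack"))
  d <- dim(stack$data)
  fs <- stack$fs
  duration_s <- d[4] / fs
  w <- window_s * fs
  st <- step_s * fs
  if (abs(w - round(w)) > 1e-8 || abs(st - round(st)) > 1e-8) {
    stopf("window_s and step_s must be integer numbers of samples at fs = %g", fs)
  }
  w <- as.integer(round(w)); st <- as.integer(round(st))
  k <- n_segments(duration_s, window_s, step_s)
  starts <- (seq_len(k) - 1L) * st  # sample offsets

  n_seg <- d[1] * k
  out <- array(0, dim = c(n_seg, d[2], d[3], w))
  labels <- integer(n_seg)
  prov <- data.frame(subject = integer(n_seg), trial = integer(n_seg),
                     window_start_s = numeric(n_seg))
  i <- 0L
  for (tr in seq_len(d[1])) {
    for (j in seq_len(k)) {
      i <- i + 1L
      out[i, , , ] <- stack$data[tr, , , (starts[j] + 1L):(starts[j] + w)]
      labels[i] <- stack$labels[tr]
      prov$subject[i] <- stack$provenance$subject[tr]
      prov$trial[i] <- stack$provenance$trial[tr]
      prov$window_start_s[i] <- starts[j] / fs
    }
  }
  structure(list(
    data = out, fs = fs, band_edges = stack$band_edges,
    labels = labels, provenance = prov,
    window_s = window_s, step_s = step_s
  ), class = "segment_set")
}
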