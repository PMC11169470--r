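#' A multichannel extracellular recording
#'
#' Container for one multi-electrode-array (MEA) recording: an `m x S` matrix
#' of voltages (one row per electrode) plus the sampling rate and the
#' sampling-timepoint / organoid labels used to assemble data increments.
#'
#' @param signals Numeric `m x S` matrix (microvolts; rows = electrodes).
#' @param fs Sampling rate in Hz.
#' @param timepoint Sampling timepoint index (chronological).
#' @param label Organoid/well identifier.
#' @param ref_channel Optional index of a reference electrode.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(signals, fs, timepoint = 1L, label = "organoid",
                          ref_channel = NULL) {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), nrow(signals) >= 1, fs > 0)
  if (!is.null(ref_channel)) {
    stopifnot(ref_channel >= 1, ref_channel <= nrow(signals))
  }
  structure(list(signals = signals, fs = fs,
                 timepoint = as.integer(timepoint), label = label,
                 ref_channel = ref_channel),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> label=%s  timepoint=%d  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$label, x$timepoint, nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  invisible(x)
}

#' High-pass filter a recording
#'
#' Removes low-frequency artifacts with an `order`-th order high-pass
#' Butterworth filter (default third order at 300 Hz). By default the filter
#' is applied forward and backward (zero phase), which avoids phase-distorting
#' transient spike shapes; set `zero_phase = FALSE` for a single causal pass.
#'
#' @param rec An `mea_recording`.
#' @param cutoff_hz Cutoff frequency in Hz (must be below Nyquist).
#' @param order Filter order.
#' @param zero_phase Use forward-backward filtering.
#' @return The filtered `mea_recording`.
#' @export
highpass <- function(rec, cutoff_hz = 300, order = 3, zero_phase = TRUE) {
  stopifnot(inherits(rec, "mea_recording"))
  if (cutoff_hz >= rec$fs / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  rec$signals <- t(apply(rec$signals, 1, function(ch) {
    if (zero_phase) signal::filtfilt(bf, ch) else
      as.numeric(signal::filter(bf, ch))
  }))
  rec
}

#' Split a recording into non-overlapping windows
#'
#' @param rec An `mea_recording`.
#' @param window_s Window length in seconds (`fs * window_s` must be an
#'   integer). Windows are anchored at the first sample; a trailing partial
#'   window is discarded.
#' @return A list of `m x (fs * window_s)` matrices (possibly empty, with a
#'   warning, when the recording is shorter than one window).
#' @export
segment_recording <- function(rec, window_s = 4) {
  stopifnot(inherits(rec, "mea_recording"))
  w <- rec$fs * window_s
  if (abs(w - round(w)) > 1e-9) {
    stop("`fs * window_s` must be an integer number of samples", call. = FALSE)
  }
  w <- as.integer(round(w))
  n_seg <- ncol(rec$signals) %/% w
  if (n_seg == 0L) {
    warning("recording shorter than one window; returning no segments")
    return(list())
  }
  lapply(seq_len(n_seg), function(j) {
    rec$signals[, ((j - 1L) * w + 1L):(j * w), drop = FALSE]
  })
}

#' FFT amplitude-spectrum features of one segment
#'
#' Computes the Fourier amplitude spectrum of every channel, keeps the first
#' half of each spectrum (the second half is redundant by conjugate symmetry
#' for real signals; the DC bin is included), concatenates the per-channel
#' half-spectra, and reduces the concatenation to exactly `k` features.
#' The default reduction averages adjacent bins (each output feature is the
#' mean of a contiguous block of amplitude bins), which is deterministic,
#' data-independent and preserves the spectral ordering; `"truncate"` keeps
#' the `k` lowest bins and `"max"` max-pools the blocks instead.
#'
#' @param block An `m x W` numeric matrix (one segment).
#' @param k Number of output features.
#' @param reduce Reduction method.
#' @return A numeric vector of length `k` (non-negative amplitudes).
#' @export
fft_features <- function(block, k = 1000L,
                         reduce = c("mean", "truncate", "max")) {
  reduce <- match.arg(reduce)
  block <- as.matrix(block)
  stopifnot(all(is.finite(block)))
  half <- ncol(block) %/% 2L
  # concatenated per-channel half-spectra (channel 1 bins, channel 2 bins, ...)
  spec <- as.numeric(vapply(seq_len(nrow(block)), function(ch) {
    Mod(stats::fft(block[ch, ]))[seq_len(half)]
  }, numeric(half)))
  if (k > length(spec)) {
    stop(sprintf("k = %d exceeds the %d available spectrum bins",
                 k, length(spec)), call. = FALSE)
  }
  if (reduce == "truncate") return(spec[seq_len(k)])
  groups <- ceiling(seq_along(spec) / (length(spec) / k))
  agg <- if (reduce == "mean") {
    tapply(spec, groups, mean)
  } else {
    tapply(spec, groups, max)
  }
  as.numeric(agg)[seq_len(k)]
}

#' Featurize a whole recording
#'
#' Convenience wrapper: high-pass filter, segment into non-overlapping
#' windows, and compute FFT features of every segment.
#'
#' @inheritParams highpass
#' @inheritParams segment_recording
#' @inheritParams fft_features
#' @param filter Apply the high-pass filter first.
#' @return A `n_segments x k` matrix of features.
#' @export
mea_features <- function(rec, k = 1000L, window_s = 4, cutoff_hz = 300,
                         order = 3, zero_phase = TRUE, filter = TRUE,
                         reduce = "mean") {
  if (filter) rec <- highpass(rec, cutoff_hz, order, zero_phase)
  blocks <- segment_recording(rec, window_s)
  if (length(blocks) == 0L) {
    return(matrix(numeric(0), 0L, k))
  }
  t(vapply(blocks, fft_features, numeric(k), k = k, reduce = reduce))
}

#' Assemble per-timepoint feature increments from recordings
#'
#' Featurizes each recording and groups the resulting segment features into
#' one increment per sampling timepoint and organoid label. Timepoints may be
#' missing for some labels; each label's increments are renumbered
#' consecutively (1, 2, ...) in chronological order, so streams with
#' different recording schedules can still be modeled jointly session by
#' session.
#'
#' @param recs List of `mea_recording` objects.
#' @param ... Passed to [mea_features()].
#' @return A named list of `ilvis_increments` objects, one per label.
#' @export
build_increments <- function(recs, ...) {
  stopifnot(is.list(recs))
  if (length(recs) == 0L) return(list())
  stopifnot(all(vapply(recs, inherits, TRUE, "mea_recording")))
  keys <- paste(vapply(recs, function(r) r$label, character(1)),
                vapply(recs, function(r) r$timepoint, 1L), sep = "\r")
  if (anyDuplicated(keys)) {
    stop("duplicate (label, timepoint) recordings", call. = FALSE)
  }
  labs <- unique(vapply(recs, function(r) r$label, character(1)))
  out <- lapply(labs, function(lab) {
    mine <- Filter(function(r) r$label == lab, recs)
    tps <- vapply(mine, function(r) r$timepoint, 1L)
    mine <- mine[order(tps)]
    incs <- lapply(seq_along(mine), function(i) {
      feats <- mea_features(mine[[i]], ...)
      list(i = i, t = seq_len(nrow(feats)), points = feats)
    })
    ks <- unique(vapply(incs, function(e) ncol(e$points), 1L))
    stopifnot(length(ks) == 1L)
    structure(list(label = lab, delta = NULL, D = ks, traj = NULL,
                   n = length(incs), increments = incs),
              class = "ilvis_increments")
  })
  names(out) <- labs
  out
}
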