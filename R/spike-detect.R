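#' Threshold-crossing spike detection
#'
#' Conventional spike-count baseline. The reference channel (if any) is
#' subtracted from every other channel, a Butterworth band-pass (default
#' 300--1000 Hz, third order) is applied, and spikes are detected as
#' negative-going crossings of a per-channel threshold
#' `k_mult * MS`, where the "median sigma" `MS` is the median of the filtered
#' signal's absolute values (set `estimator = "mad"` for the 0.6745-scaled
#' MAD noise estimate instead). Crossings within the refractory window after
#' an accepted event are collapsed into that event.
#'
#' Because the threshold scales with the signal, detection is equivariant to
#' positive rescaling of the input. An all-zero channel yields a threshold of
#' 0 and no detections.
#'
#' @param rec An `mea_recording`.
#' @param band Band-pass corner frequencies in Hz.
#' @param k_mult Threshold multiplier (negative: negative-going crossings).
#' @param refractory_ms Dead time after each accepted event, in milliseconds.
#' @param order Butterworth filter order.
#' @param estimator `"median_sigma"` (median of absolute values) or `"mad"`.
#' @return A list of class `spike_trains`: one entry per non-reference
#'   channel with fields `channel`, `indices` (sorted sample indices),
#'   `threshold`.
#' @export
detect_spikes <- function(rec, band = c(300, 1000), k_mult = -4.0,
                          refractory_ms = 1, order = 3,
                          estimator = c("median_sigma", "mad")) {
  stopifnot(inherits(rec, "mea_recording"))
  estimator <- match.arg(estimator)
  if (band[1] <= 0 || band[2] >= rec$fs / 2 || band[1] >= band[2]) {
    stop("`band` must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  if (k_mult >= 0) {
    stop("`k_mult` must be negative (negative-going threshold)", call. = FALSE)
  }
  sig <- rec$signals
  channels <- seq_len(nrow(sig))
  if (!is.null(rec$ref_channel)) {
    ref <- sig[rec$ref_channel, ]
    sig <- sweep(sig, 2, ref)
    channels <- setdiff(channels, rec$ref_channel)
  }
  bf <- signal::butter(order, band / (rec$fs / 2), type = "pass")
  refr <- max(1L, as.integer(round(refractory_ms / 1000 * rec$fs)))
  trains <- lapply(channels, function(ch) {
    x <- signal::filtfilt(bf, sig[ch, ])
    ms <- if (estimator == "median_sigma") {
      stats::median(abs(x))
    } else {
      stats::median(abs(x)) / 0.6745
    }
    thr <- k_mult * ms
    idx <- integer(0)
    if (thr < 0) {
      cross <- which(x[-1] < thr & x[-length(x)] >= thr) + 1L
      last <- -Inf
      keep <- logical(length(cross))
      for (q in seq_along(cross)) {
        if (cross[q] - last >= refr) {
          keep[q] <- TRUE
          last <- cross[q]
        }
      }
      idx <- cross[keep]
    }
    list(channel = ch, indices = idx, threshold = thr)
  })
  structure(trains, class = "spike_trains", fs = rec$fs,
            n_samples = ncol(rec$signals))
}

#' Per-channel spike counts and rates
#'
#' @param trains A `spike_trains` object from [detect_spikes()].
#' @return A data frame with columns `channel`, `n_spikes`, `rate_hz`.
#' @export
spike_counts <- function(trains) {
  stopifnot(inherits(trains, "spike_trains"))
  dur <- attr(trains, "n_samples") / attr(trains, "fs")
  data.frame(channel = vapply(trains, `[[`, 1L, "channel"),
             n_spikes = vapply(trains, function(t) length(t$indices), 1L),
             rate_hz = vapply(trains, function(t) length(t$indices), 1L) / dur)
}
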