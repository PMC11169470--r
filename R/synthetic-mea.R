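#' Specification of a surrogate longitudinal MEA experiment
#'
#' Describes a synthetic multichannel extracellular recording series used to
#' exercise the full preprocess / embed / trace / distance pipeline without
#' experimental data. Each channel is Gaussian noise plus Poisson-timed
#' biphasic spike waveforms; the per-timepoint firing-rate schedule provides
#' the longitudinal drift (emulating the gradual increase in electrical
#' activity of maturing neural cultures), optionally together with a
#' spike-amplitude schedule.
#'
#' The default sampling rate (5 kHz) is reduced relative to typical MEA
#' hardware (25 kHz) to keep desk-scale runs fast; the waveform timescale
#' (about 1 ms) is unchanged, so detection behaves the same.
#'
#' @param m Number of electrodes.
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording length per timepoint, seconds.
#' @param rates_hz Per-timepoint mean firing rate per channel (length = number
#'   of timepoints, all >= 0).
#' @param amp_uV Spike amplitude in microvolts (positive number; the waveform's
#'   main lobe is negative, as for extracellular spikes). May be a vector per
#'   timepoint to add amplitude drift.
#' @param noise_sd Gaussian background noise SD, microvolts.
#' @param label Organoid label carried into the recordings.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(m = 9L, fs = 5000, duration_s = 60,
                           rates_hz = c(1, 2, 4, 7, 10),
                           amp_uV = 50, noise_sd = 5,
                           label = "surrogate") {
  n <- length(rates_hz)
  stopifnot(m >= 1, fs > 0, duration_s > 0, n >= 2, all(rates_hz >= 0),
            all(amp_uV > 0), noise_sd >= 0)
  amp_uV <- rep_len(amp_uV, n)
  structure(list(m = as.integer(m), fs = fs, duration_s = duration_s,
                 rates_hz = rates_hz, amp_uV = amp_uV, noise_sd = noise_sd,
                 n = n, label = label),
            class = "surrogate_spec")
}

# Biphasic extracellular spike template (~1 ms): negative main lobe followed
# by a smaller positive rebound (difference of Gaussians).
spike_template <- function(fs, amp_uV = 50, width_ms = 1) {
  len <- max(8L, as.integer(round(2.5 * width_ms / 1000 * fs)))
  tt <- seq_len(len) / fs * 1000  # ms
  s1 <- width_ms / 6
  s2 <- width_ms / 3
  main <- exp(-(tt - width_ms * 0.8)^2 / (2 * s1^2))
  rebound <- exp(-(tt - width_ms * 1.5)^2 / (2 * s2^2))
  w <- -main + 0.4 * rebound
  amp_uV * w / max(abs(w))
}

#' Generate surrogate MEA recordings
#'
#' @param spec A [surrogate_spec()].
#' @return A list of [mea_recording()] objects, one per timepoint, in
#'   chronological order. Deterministic given the RNG state (`set.seed()`).
#'   Each recording carries the injected ground truth in its `spike_times`
#'   field (a list of per-channel sample indices of the waveform onsets),
#'   for detector-validation use.
#' @export
generate_surrogate <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  S <- as.integer(round(spec$fs * spec$duration_s))
  lapply(seq_len(spec$n), function(i) {
    tmpl <- spike_template(spec$fs, spec$amp_uV[i])
    len <- length(tmpl)
    sig <- matrix(0, spec$m, S)
    truth <- vector("list", spec$m)
    for (ch in seq_len(spec$m)) {
      x <- if (spec$noise_sd > 0) stats::rnorm(S, sd = spec$noise_sd) else
        numeric(S)
      n_sp <- stats::rpois(1, spec$rates_hz[i] * spec$duration_s)
      starts <- integer(0)
      if (n_sp > 0 && S > len) {
        starts <- sort(sample.int(S - len, n_sp, replace = TRUE))
        for (st in starts) {
          span <- st:(st + len - 1L)
          x[span] <- x[span] + tmpl
        }
      }
      truth[[ch]] <- starts
      sig[ch, ] <- x
    }
    rec <- mea_recording(sig, fs = spec$fs, timepoint = i, label = spec$label)
    rec$spike_times <- truth
    rec
  })
}

#' Fraction of injected spikes recovered by a detector
#'
#' Matches each ground-truth spike onset of a surrogate recording to the
#' nearest detection within `tol_ms` and returns the per-channel recall.
#'
#' @param rec A surrogate [mea_recording()] with a `spike_times` field.
#' @param trains The [detect_spikes()] output for the same recording.
#' @param tol_ms Matching tolerance in milliseconds.
#' @return A numeric vector of per-channel recall values in \[0, 1\]
#'   (`NaN` for channels without injected spikes).
#' @export
spike_recovery <- function(rec, trains, tol_ms = 2) {
  stopifnot(inherits(rec, "mea_recording"), !is.null(rec$spike_times),
            inherits(trains, "spike_trains"))
  tol <- tol_ms / 1000 * rec$fs
  vapply(seq_along(trains), function(q) {
    ch <- trains[[q]]$channel
    truth <- rec$spike_times[[ch]]
    if (length(truth) == 0L) return(NaN)
    det <- trains[[q]]$indices
    if (length(det) == 0L) return(0)
    hit <- vapply(truth, function(s) any(abs(det - s) <= tol), logical(1))
    mean(hit)
  }, numeric(1))
}
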