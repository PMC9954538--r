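# Epoching and band-pass preprocessing of continuous recordings.
#
# Defaults reproduce the driving-task segmentation: a 1500 ms window from
# -1300 ms to +200 ms around each response marker at 200 Hz is 300 samples;
# the first 100 ms serve as baseline and are discarded after the segmentwise
# baseline correction, leaving 280 time points. Keeping the baseline span
# (discard_baseline = FALSE) yields the full 300.

#' Epoching configuration
#'
#' @param target_window_ms c(start, end) of the target window relative to the
#'   response marker, in ms.
#' @param baseline_ms initial span of each segment used for baseline
#'   correction (its mean is subtracted channelwise), in ms.
#' @param discard_baseline drop the baseline span from the output (default
#'   TRUE; at 200 Hz this turns the 1500 ms window into 280 time points).
#' @param nontarget_window_ms,nontarget_step_ms sliding-window length and
#'   step for nontarget segments, in ms.
#' @param nontarget_exclusion_ms minimum distance of a nontarget window from
#'   any marker (symmetric, both sides), in ms.
#' @param excluded_channels channel names dropped before output (e.g. the
#'   ocular-artifact-prone frontal electrodes).
#' @param balance_classes subsample nontargets (seeded, uniform) to the
#'   target count.
#' @param seed seed for the balancing subsample.
#' @return an object of class `epoching_config`.
#' @export
epoching_config <- function(target_window_ms = c(-1300, 200),
                            baseline_ms = 100, discard_baseline = TRUE,
                            nontarget_window_ms = 1500,
                            nontarget_step_ms = 500,
                            nontarget_exclusion_ms = 3000,
                            excluded_channels = c("FP1", "FP2", "AF3", "AF4"),
                            balance_classes = TRUE, seed = 1L) {
  if (diff(target_window_ms) <= 0 || nontarget_window_ms <= 0 ||
      nontarget_step_ms <= 0)
    stop_eegtrm("window lengths and steps must be positive",
                class = "eegtrm_config_error")
  if (nontarget_exclusion_ms < 0 || baseline_ms < 0)
    stop_eegtrm("baseline and exclusion spans must be >= 0",
                class = "eegtrm_config_error")
  if (anyDuplicated(excluded_channels))
    stop_eegtrm("excluded channels must be distinct",
                class = "eegtrm_config_error")
  structure(list(target_window_ms = target_window_ms,
                 baseline_ms = baseline_ms,
                 discard_baseline = isTRUE(discard_baseline),
                 nontarget_window_ms = nontarget_window_ms,
                 nontarget_step_ms = nontarget_step_ms,
                 nontarget_exclusion_ms = nontarget_exclusion_ms,
                 excluded_channels = as.character(excluded_channels),
                 balance_classes = isTRUE(balance_classes),
                 seed = as.integer(seed)),
            class = "epoching_config")
}

keep_channels <- function(record, excluded) {
  keep <- !(record$channel_names %in% excluded)
  list(data = record$data[keep, , drop = FALSE],
       names = record$channel_names[keep])
}

# cut fixed-length windows at given start samples; baseline-correct on the
# first nb samples and optionally discard them
cut_segments <- function(data, starts, len, nb, discard) {
  n_ch <- nrow(data)
  out_len <- if (discard) len - nb else len
  seg <- array(0, c(length(starts), n_ch, out_len))
  for (i in seq_along(starts)) {
    w <- data[, starts[i] + seq_len(len) - 1L, drop = FALSE]
    if (nb > 0L) {
      w <- w - rowMeans(w[, seq_len(nb), drop = FALSE])
      if (discard) w <- w[, -seq_len(nb), drop = FALSE]
    }
    seg[i, , ] <- w
  }
  seg
}

#' Cut target segments around response markers
#'
#' One segment per marker whose window lies fully inside the record (others
#' are skipped with a warning). Each segment is baseline-corrected channelwise
#' on its first `baseline_ms`; with `discard_baseline` the baseline span is
#' then removed. Excluded channels are dropped by name, order preserved.
#'
#' @param record an [eeg_record].
#' @param markers response-marker times in seconds; default: the record's
#'   markers of type `"response"`.
#' @param config an [epoching_config].
#' @return an [epoch_set] labeled `"target"`.
#' @export
epoch_targets <- function(record, markers = NULL,
                          config = epoching_config()) {
  fs <- record$sampling_rate
  if (is.null(markers))
    markers <- record$markers$time_s[record$markers$type == "response"]
  len <- round(diff(config$target_window_ms) / 1000 * fs)
  nb <- round(config$baseline_ms / 1000 * fs)
  starts <- round((markers + config$target_window_ms[1L] / 1000) * fs) + 1L
  ok <- starts >= 1L & (starts + len - 1L) <= ncol(record$data)
  if (any(!ok))
    warning(sprintf("%d marker(s) too close to the record edge; skipped",
                    sum(!ok)))
  kc <- keep_channels(record, config$excluded_channels)
  seg <- cut_segments(kc$data, starts[ok], len, nb, config$discard_baseline)
  epoch_set(seg, rep("target", sum(ok)), fs, kc$names,
            metadata = list(epoching = unclass(config), kind = "target"))
}

# admissible nontarget start times (seconds): step grid from 0, window fully
# inside the record and >= exclusion from every marker
nontarget_starts <- function(total_s, marker_s, win_s, step_s, excl_s) {
  starts <- seq(0, total_s - win_s, by = step_s)
  if (length(marker_s)) {
    ok <- vapply(starts, function(s)
      all(s + win_s <= marker_s - excl_s | s >= marker_s + excl_s), TRUE)
    starts <- starts[ok]
  }
  starts
}

#' Cut nontarget segments away from all markers
#'
#' Sliding windows (default 1500 ms length, 500 ms step) that keep at least
#' `nontarget_exclusion_ms` distance from every marker of any type; baseline
#' handling and channel exclusion as for targets. With `balance_classes` and
#' `n_target`, a seeded uniform subsample of `n_target` windows is returned.
#'
#' @inheritParams epoch_targets
#' @param markers marker times in seconds to stay away from; default: all of
#'   the record's markers.
#' @param n_target target-segment count to balance against (optional).
#' @return an [epoch_set] labeled `"nontarget"` (empty, with a warning, if no
#'   window is admissible).
#' @export
epoch_nontargets <- function(record, markers = NULL,
                             config = epoching_config(), n_target = NULL) {
  fs <- record$sampling_rate
  if (is.null(markers)) markers <- record$markers$time_s
  total_s <- ncol(record$data) / fs
  win_s <- config$nontarget_window_ms / 1000
  starts_s <- nontarget_starts(total_s, markers, win_s,
                               config$nontarget_step_ms / 1000,
                               config$nontarget_exclusion_ms / 1000)
  if (config$balance_classes && !is.null(n_target) &&
      length(starts_s) > n_target)
    starts_s <- sort(with_seed(config$seed,
                               sample(starts_s, n_target)))
  kc <- keep_channels(record, config$excluded_channels)
  len <- round(win_s * fs)
  nb <- round(config$baseline_ms / 1000 * fs)
  if (!length(starts_s)) {
    warning("no admissible nontarget windows")
    out_len <- if (config$discard_baseline) len - nb else len
    return(epoch_set(array(0, c(0L, nrow(kc$data), out_len)),
                     character(0), fs, kc$names,
                     metadata = list(epoching = unclass(config),
                                     kind = "nontarget")))
  }
  seg <- cut_segments(kc$data, round(starts_s * fs) + 1L, len, nb,
                      config$discard_baseline)
  epoch_set(seg, rep("nontarget", length(starts_s)), fs, kc$names,
            metadata = list(epoching = unclass(config), kind = "nontarget"))
}

#' Cut fixed-duration trialwise segments
#'
#' Uses the entire trial duration from each onset (e.g. 4 s at 250 Hz gives
#' 1000 time points); no baseline correction is applied.
#'
#' @param record an [eeg_record].
#' @param trial_onsets onset times in seconds.
#' @param duration_s trial duration in seconds (> 0).
#' @param config an [epoching_config] (only `excluded_channels` is used).
#' @param labels optional per-trial labels, recycled against the kept onsets.
#' @return an [epoch_set].
#' @export
epoch_trialwise <- function(record, trial_onsets, duration_s,
                            config = epoching_config(excluded_channels = character(0)),
                            labels = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_eegtrm("trial duration must be > 0 (got %s)", duration_s,
                class = "eegtrm_config_error")
  fs <- record$sampling_rate
  len <- round(duration_s * fs)
  starts <- round(trial_onsets * fs) + 1L
  ok <- starts >= 1L & (starts + len - 1L) <= ncol(record$data)
  if (any(!ok))
    warning(sprintf("%d onset(s) too close to the record end; skipped",
                    sum(!ok)))
  kc <- keep_channels(record, config$excluded_channels)
  seg <- cut_segments(kc$data, starts[ok], len, 0L, FALSE)
  if (!is.null(labels)) labels <- rep_len(labels, length(ok))[ok]
  epoch_set(seg, labels, fs, kc$names,
            metadata = list(kind = "trialwise", duration_s = duration_s))
}

#' Band-pass filter and downsample a continuous record
#'
#' Zero-phase (forward-backward) Butterworth filtering of order 4, followed
#' by resampling: plain decimation when the target rate divides the original,
#' polyphase resampling otherwise. Marker times (in seconds) are unchanged.
#'
#' @param record an [eeg_record].
#' @param low_hz,high_hz passband edges; `0 <= low < high < ` original
#'   Nyquist. `low_hz = 0` gives a pure low-pass.
#' @param target_rate output sampling rate (default: keep the original).
#' @return the filtered, resampled [eeg_record].
#' @export
bandpass_downsample <- function(record, low_hz, high_hz,
                                target_rate = record$sampling_rate) {
  fs <- record$sampling_rate
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= fs / 2)
    stop_eegtrm("need 0 <= low < high < %g (got %g, %g)", fs / 2,
                low_hz, high_hz, class = "eegtrm_config_error")
  if (high_hz > target_rate / 2)
    stop_eegtrm("band edge %g Hz exceeds the Nyquist rate after resampling to %g Hz",
                high_hz, target_rate, class = "eegtrm_config_error")
  filt <- if (low_hz > 0)
    signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  else signal::butter(4, high_hz / (fs / 2), type = "low")
  x <- t(apply(record$data, 1L, function(ch) signal::filtfilt(filt, ch)))
  if (target_rate != fs) {
    if (fs %% target_rate == 0) {
      dec <- fs %/% target_rate
      x <- x[, seq(1L, ncol(x), by = dec), drop = FALSE]
    } else {
      rr <- gcd_ratio(target_rate, fs)
      x <- t(apply(x, 1L, function(ch)
        signal::resample(ch, rr[1L], rr[2L])))
    }
  }
  eeg_record(x, target_rate, record$channel_names, record$markers,
             metadata = c(record$metadata,
                          list(filter = sprintf(
                            "butterworth order 4, zero-phase, %g-%g Hz",
                            low_hz, high_hz))))
}

gcd_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}
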