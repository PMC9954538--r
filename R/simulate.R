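# Synthetic EEG with class-dependent spatial topographies: each class owns a
# focus cell on the montage grid; its trials carry a band-limited oscillatory
# burst whose amplitude decays with grid distance from the focus, superposed
# on 1/f-shaped plus white noise. Spatial decay is measured in grid-cell
# distance (the unit the topographic module actually sees), not scalp arc
# length.

#' Configuration for the synthetic EEG generator
#'
#' @param montage a [montage_grid] (defines channel count and focus geometry).
#' @param n_classes number of classes (each gets a distinct focus cell).
#' @param trials_per_class trials per class (labels come out exactly
#'   balanced).
#' @param TP time points per trial.
#' @param sampling_rate sampling rate in Hz.
#' @param oscillation_band frequency range (Hz) of the class bursts; each
#'   trial draws its carrier frequency uniformly from this band. Must lie
#'   within (0, sampling_rate/2).
#' @param snr linear signal-to-noise ratio: RMS of the burst at its focus
#'   channel over the per-channel noise RMS. `Inf` gives noiseless trials.
#' @param spatial_spread Gaussian decay scale of burst amplitude across the
#'   grid, in grid-cell units.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(montage, n_classes = 2L, trials_per_class = 40L,
                       TP = 280L, sampling_rate = 200,
                       oscillation_band = c(8, 13), snr = 5,
                       spatial_spread = 1.5, seed = 1L) {
  n_classes <- as.integer(n_classes)
  trials_per_class <- as.integer(trials_per_class)
  TP <- as.integer(TP)
  if (n_classes < 1L || trials_per_class < 1L || TP < 1L ||
      sampling_rate <= 0)
    stop_eegtrm("all counts and the sampling rate must be positive",
                class = "eegtrm_config_error")
  if (!(snr > 0))
    stop_eegtrm("snr must be > 0 (got %s)", snr,
                class = "eegtrm_config_error")
  if (oscillation_band[1L] <= 0 || oscillation_band[2L] >= sampling_rate / 2 ||
      oscillation_band[1L] > oscillation_band[2L])
    stop_eegtrm("oscillation band must lie within (0, sampling_rate/2)",
                class = "eegtrm_config_error")
  if (length(montage$channel_names) < n_classes)
    stop_eegtrm("montage has %d channels; cannot place %d distinct foci",
                length(montage$channel_names), n_classes,
                class = "eegtrm_config_error")
  structure(list(montage = montage, n_classes = n_classes,
                 trials_per_class = trials_per_class, TP = TP,
                 sampling_rate = sampling_rate,
                 oscillation_band = as.numeric(oscillation_band),
                 snr = snr, spatial_spread = spatial_spread,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic focus channels: order channels left-to-right (then
# front-to-back) across the grid and take evenly spaced ones, so foci of
# different classes sit far apart
sim_foci <- function(montage, n_classes) {
  a <- montage$assignments
  ord <- order(a[, 2L], a[, 1L])
  pick <- round(seq(1L, length(ord), length.out = n_classes + 2L))
  ord[pick[seq_len(n_classes) + 1L]]
}

# 1/f-amplitude-shaped noise (spectral exponent 1 in power), n samples
pink_noise <- function(n, fs) {
  spec <- stats::fft(stats::rnorm(n))
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[1L] <- f[2L]
  shape <- 1 / sqrt(pmin(f, fs - f))   # mirrored for negative frequencies
  shape[1L] <- 0                       # no DC
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# common-mode 1/f at 30% amplitude plus independent white noise, unit RMS
# per channel (approximately; exact normalization applied by caller)
sim_noise <- function(C, n, fs) {
  common <- pink_noise(n, fs)
  w <- matrix(stats::rnorm(C * n), C, n)
  x <- 0.3 * matrix(common, C, n, byrow = TRUE) + w
  x / sqrt(1 + 0.3^2)
}

#' Simulate labeled EEG epochs with class-specific topographies
#'
#' @param config a [sim_config].
#' @param components also return the separate signal and noise arrays
#'   (useful for spectral checks); the epochs are unchanged.
#' @return an [epoch_set] of `n_classes * trials_per_class` trials (integer
#'   labels `1..n_classes`), or, with `components = TRUE`, a list with
#'   elements `epochs`, `signal` and `noise`.
#' @export
#' @examples
#' m <- load_montage("ebdsdd-7x9")
#' es <- simulate_epochs(sim_config(m, trials_per_class = 5, TP = 100))
#' dim(es)
simulate_epochs <- function(config, components = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$montage
  C <- length(m$channel_names)
  TP <- config$TP; fs <- config$sampling_rate
  n_trials <- config$n_classes * config$trials_per_class
  foci <- sim_foci(m, config$n_classes)
  # per-class channel amplitude profiles (Gaussian in grid distance)
  amp <- matrix(0, C, config$n_classes)
  for (k in seq_len(config$n_classes)) {
    fc <- m$assignments[foci[k], ]
    d2 <- (m$assignments[, 1L] - fc[1L])^2 + (m$assignments[, 2L] - fc[2L])^2
    amp[, k] <- exp(-d2 / (2 * config$spatial_spread^2))
  }
  labels <- rep(seq_len(config$n_classes), each = config$trials_per_class)
  tt <- (seq_len(TP) - 1L) / fs
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = TP))  # Hann burst
  sig <- array(0, c(n_trials, C, TP))
  noi <- array(0, c(n_trials, C, TP))
  with_seed(config$seed, {
    for (i in seq_len(n_trials)) {
      f0 <- stats::runif(1L, config$oscillation_band[1L],
                         config$oscillation_band[2L])
      ph <- stats::runif(1L, 0, 2 * pi)
      carrier <- sin(2 * pi * f0 * tt + ph) * env
      sig[i, , ] <- outer(amp[, labels[i]], carrier)
      if (is.finite(config$snr)) {
        rms_sig <- sqrt(mean(carrier^2))            # focus amplitude is 1
        nz <- sim_noise(C, TP, fs)
        nz <- nz / sqrt(mean(nz^2))                 # unit per-channel RMS
        noi[i, , ] <- nz * rms_sig / config$snr
      }
    }
  })
  es <- epoch_set(sig + noi, labels, fs, m$channel_names,
                  metadata = list(generator = "eegtrm-sim",
                                  foci = m$channel_names[foci],
                                  snr = config$snr,
                                  oscillation_band = config$oscillation_band,
                                  spatial_spread = config$spatial_spread,
                                  seed = config$seed))
  if (components) list(epochs = es, signal = sig, noise = noi) else es
}

#' Continuous EEG record container
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate Hz.
#' @param channel_names ordered channel identifiers.
#' @param markers data.frame with columns `time_s` and `type` (e.g.
#'   `"stimulus"`, `"response"`), times in seconds from record start.
#' @param metadata optional named list.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(data, sampling_rate, channel_names = NULL,
                       markers = NULL, metadata = list()) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_eegtrm("%d channel names for %d channels", length(channel_names),
                nrow(data), class = "eegtrm_dimension_error")
  if (is.null(markers))
    markers <- data.frame(time_s = numeric(0), type = character(0))
  structure(list(data = data, sampling_rate = as.numeric(sampling_rate),
                 channel_names = as.character(channel_names),
                 markers = markers, metadata = metadata),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz, %d markers\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$markers)))
  invisible(x)
}

#' Generate a continuous record with embedded event markers
#'
#' Emulates an event-driven recording: stimulus markers are spaced by gaps
#' drawn uniformly from `gap_range_s`, each followed by a response marker
#' after a uniform reaction time, on top of 1/f plus white background noise.
#' Give either `n_events` or `duration_s` (with `duration_s`, as many events
#' as fit are placed).
#'
#' @param montage a [montage_grid] (defines the channels).
#' @param n_events number of stimulus/response marker pairs, or `NULL`.
#' @param duration_s record length in seconds, or `NULL` (derived from the
#'   last event plus `tail_s`).
#' @param sampling_rate Hz.
#' @param gap_range_s uniform range of inter-stimulus gaps, seconds.
#' @param rt_range_s uniform range of stimulus-to-response times, seconds.
#' @param min_gap_s smallest admissible gap (e.g. the epoching window
#'   length); a `gap_range_s` below it is a configuration error.
#' @param offset_s time of the first stimulus.
#' @param tail_s silence appended after the last event.
#' @param seed integer seed.
#' @return an [eeg_record] with `"stimulus"` and `"response"` markers.
#' @export
make_event_stream <- function(montage, n_events = NULL, duration_s = NULL,
                              sampling_rate = 200,
                              gap_range_s = c(20, 40),
                              rt_range_s = c(0.3, 0.8),
                              min_gap_s = 1.5, offset_s = 5, tail_s = 5,
                              seed = 1L) {
  if (is.null(n_events) && is.null(duration_s))
    stop_eegtrm("give n_events or duration_s",
                class = "eegtrm_config_error")
  if (gap_range_s[1L] > gap_range_s[2L] || gap_range_s[1L] < min_gap_s)
    stop_eegtrm("gap range [%g, %g] s is below the minimum spacing %g s",
                gap_range_s[1L], gap_range_s[2L], min_gap_s,
                class = "eegtrm_config_error")
  C <- length(montage$channel_names)
  with_seed(seed, {
    stim <- numeric(0)
    t <- offset_s
    if (!is.null(n_events)) {
      if (n_events > 0L) for (i in seq_len(n_events)) {
        stim <- c(stim, t)
        t <- t + stats::runif(1L, gap_range_s[1L], gap_range_s[2L])
      }
    } else {
      repeat {
        if (t + tail_s > duration_s) break
        stim <- c(stim, t)
        t <- t + stats::runif(1L, gap_range_s[1L], gap_range_s[2L])
      }
    }
    resp <- stim + stats::runif(length(stim), rt_range_s[1L], rt_range_s[2L])
    total_s <- duration_s %||% (max(c(offset_s, resp)) + tail_s)
    n <- ceiling(total_s * sampling_rate)
    bg <- sim_noise(C, n, sampling_rate)
    markers <- data.frame(
      time_s = c(stim, resp),
      type = rep(c("stimulus", "response"), c(length(stim), length(resp))))
    markers <- markers[order(markers$time_s), , drop = FALSE]
    rownames(markers) <- NULL
    eeg_record(bg, sampling_rate, montage$channel_names, markers,
               metadata = list(generator = "eegtrm-sim", seed = seed))
  })
}
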