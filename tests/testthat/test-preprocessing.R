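# Epoching and filtering against independent oracles.

# a 59-channel record in the driving-task configuration: the four frontal
# channels to be excluded plus the 55 of the shipped layout
make_ebdsdd_record <- function(seconds = 120, fs = 200, n_events = 3,
                               seed = 1) {
  m9 <- load_montage("ebdsdd-7x9")
  ch <- c("FP1", "FP2", "AF3", "AF4", m9$channel_names)
  set.seed(seed)
  n <- seconds * fs
  stim <- seq(20, seconds - 10, length.out = n_events)
  resp <- stim + 0.5
  eeg_record(matrix(rnorm(length(ch) * n), length(ch), n), fs, ch,
             data.frame(time_s = c(stim, resp),
                        type = rep(c("stimulus", "response"), each = n_events)))
}

test_that("target epoching reproduces the 55 x 280 evaluation shape", {
  rec <- make_ebdsdd_record()
  tg <- epoch_targets(rec)   # default config: -1300..+200 ms, 100 ms baseline
  expect_equal(dim(tg), c(3, 55, 280))
  expect_false(any(c("FP1", "FP2", "AF3", "AF4") %in% tg$channel_names))
  # keeping the baseline span yields the full 1500 ms worth of samples
  tg300 <- epoch_targets(rec, config = epoching_config(discard_baseline = FALSE))
  expect_equal(dim(tg300)[3], 300)
  # the baseline-span mean is exactly zero after correction
  nb <- 0.1 * rec$sampling_rate
  bl_means <- apply(tg300$data[, , seq_len(nb)], c(1, 2), mean)
  expect_lt(max(abs(bl_means)), 1e-12)
  # channel exclusion preserves the order of the remainder
  expect_equal(tg$channel_names,
               setdiff(rec$channel_names, c("FP1", "FP2", "AF3", "AF4")))
})

test_that("a constant record gives all-zero segments after baseline correction", {
  rec <- eeg_record(matrix(7.5, 4, 2000), 200, letters[1:4],
                    data.frame(time_s = 5, type = "response"))
  tg <- epoch_targets(rec, config = epoching_config(
    excluded_channels = character(0)))
  expect_equal(max(abs(tg$data)), 0)
})

test_that("markers too close to the record edge are skipped with a warning", {
  rec <- eeg_record(matrix(rnorm(4 * 1000), 4, 1000), 200, letters[1:4],
                    data.frame(time_s = c(0.5, 3), type = "response"))
  expect_warning(tg <- epoch_targets(rec, config = epoching_config(
    excluded_channels = character(0))), "skipped")
  expect_equal(dim(tg)[1], 1L)
})

test_that("nontarget window counts match the interval-arithmetic oracle", {
  cfg <- epoching_config(excluded_channels = character(0))
  # the worked layout: markers at 10 s and 40 s in a 60 s record
  rec <- eeg_record(matrix(0, 2, 60 * 100), 100, c("a", "b"),
                    data.frame(time_s = c(10, 40),
                               type = c("response", "response")))
  nt <- suppressWarnings(epoch_nontargets(rec, config = cfg))
  n_oracle <- oracle_nontarget_count(60, c(10, 40), 1.5, 0.5, 3)
  expect_equal(dim(nt)[1], n_oracle)
  # admissible windows stay >= 3 s from every marker
  # 50 random marker layouts
  for (i in 1:50) {
    set.seed(i)
    total <- runif(1, 30, 90)
    mk <- sort(runif(sample(0:5, 1), 0, total))
    rec_i <- eeg_record(matrix(0, 1, round(total * 100)), 100, "a",
                        if (length(mk)) data.frame(time_s = mk,
                                                   type = "stimulus")
                        else NULL)
    nt_i <- suppressWarnings(epoch_nontargets(rec_i, config = cfg))
    expect_equal(dim(nt_i)[1],
                 oracle_nontarget_count(ncol(rec_i$data) / 100, mk,
                                        1.5, 0.5, 3))
  }
})

test_that("class balancing subsamples nontargets to the target count", {
  rec <- eeg_record(matrix(rnorm(2 * 12000), 2, 12000), 100, c("a", "b"),
                    data.frame(time_s = 60, type = "response"))
  cfg <- epoching_config(excluded_channels = character(0))
  nt_all <- epoch_nontargets(rec, config = cfg)
  expect_gt(dim(nt_all)[1], 50)
  nt5 <- epoch_nontargets(rec, config = cfg, n_target = 5)
  expect_equal(dim(nt5)[1], 5L)
  # an exclusion zone covering everything leaves an empty set
  cfg_all <- epoching_config(excluded_channels = character(0),
                             nontarget_exclusion_ms = 300000)
  expect_warning(nt0 <- epoch_nontargets(rec, config = cfg_all),
                 "no admissible")
  expect_equal(dim(nt0)[1], 0L)
})

test_that("trialwise epoching reproduces the 44 x 1000 evaluation shape", {
  set.seed(2)
  ch <- load_montage("hgd-7x7")$channel_names
  rec <- eeg_record(matrix(rnorm(44 * 30 * 250), 44, 30 * 250), 250, ch)
  tw <- epoch_trialwise(rec, trial_onsets = c(1, 6, 11, 16), duration_s = 4)
  expect_equal(dim(tw), c(4, 44, 1000))
  tw1 <- epoch_trialwise(rec, trial_onsets = c(1, 6), duration_s = 1)
  expect_equal(dim(tw1)[3], 250)
  expect_error(epoch_trialwise(rec, 1, duration_s = 0),
               class = "eegtrm_config_error")
  expect_warning(epoch_trialwise(rec, c(1, 29), duration_s = 4), "skipped")
})

test_that("band-pass filtering passes a 10 Hz probe, stops 1 Hz and kills DC", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)[-1]
  probe10 <- sin(2 * pi * 10 * t)
  probe1 <- sin(2 * pi * 1 * t)
  rec <- eeg_record(rbind(probe10, probe1, 1), fs, c("p10", "p1", "dc"))
  out <- bandpass_downsample(rec, 4, 125, target_rate = 250)
  expect_equal(out$sampling_rate, 250)
  expect_equal(ncol(out$data), length(t) / 2)
  core <- seq(round(0.25 * ncol(out$data)), round(0.75 * ncol(out$data)))
  amp10 <- sqrt(2 * mean(out$data[1, core]^2))
  expect_lt(abs(amp10 - 1), 0.01)                       # within 1%
  amp1 <- sqrt(2 * mean(out$data[2, core]^2))
  expect_gt(-20 * log10(amp1 / 1), 20)                  # >= 20 dB down
  expect_lt(max(abs(out$data[3, core])), 1e-3)          # DC rejected
  expect_error(bandpass_downsample(rec, 4, 260),   # above original Nyquist
               class = "eegtrm_config_error")
  expect_error(bandpass_downsample(rec, 4, 150, target_rate = 250),
               class = "eegtrm_config_error")
})

test_that("continuous records round-trip through the plain-text container", {
  m <- make_random_montage(3, 2, 2, seed = 11)
  rec <- make_event_stream(m, n_events = 2, sampling_rate = 50,
                           gap_range_s = c(5, 8), seed = 12)
  stem <- tempfile()
  write_record(rec, stem)
  rec2 <- read_record(stem)
  expect_equal(rec2$data, rec$data, tolerance = 1e-12)
  expect_equal(rec2$markers$time_s, rec$markers$time_s)
  expect_equal(rec2$markers$type, rec$markers$type)
  expect_equal(rec2$sampling_rate, rec$sampling_rate)
  expect_equal(rec2$channel_names, rec$channel_names)
})
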