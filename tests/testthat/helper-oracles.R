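# Shared test helpers: independent oracles and fixture builders (all
# fixtures are generated in code).

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_arr <- function(...) {
  d <- c(...)
  array(stats::rnorm(prod(d)), d)
}

# random injective channel-to-cell assignment
make_random_montage <- function(C, H, W, seed = 1) {
  set.seed(seed)
  cells <- sample(H * W, C) - 1L
  montage_grid(sprintf("ch%02d", seq_len(C)), H, W,
               cbind(cells %% H, cells %/% H),
               name = sprintf("rand-%dx%d-%d", H, W, C))
}

# admissible nontarget window starts by interval arithmetic (independent of
# the package's step-grid filter): the allowed region for a window start is
# [0, total - win] minus the union of (m - excl - win, m + excl) over markers
oracle_nontarget_count <- function(total_s, marker_s, win_s, step_s, excl_s) {
  starts <- seq(0, total_s - win_s, by = step_s)
  if (!length(marker_s)) return(length(starts))
  blocked <- rep(FALSE, length(starts))
  for (m in marker_s)
    blocked <- blocked | (starts > m - excl_s - win_s & starts < m + excl_s)
  sum(!blocked)
}

# tiny montage + epochs for fast training tests
tiny_training_set <- function(seed = 1, trials_per_class = 8, TP = 40) {
  m <- make_random_montage(6, 3, 3, seed = 99)
  simulate_epochs(sim_config(m, n_classes = 2,
                             trials_per_class = trials_per_class, TP = TP,
                             sampling_rate = 100,
                             oscillation_band = c(8, 12), snr = 8,
                             spatial_spread = 1, seed = seed))
}
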