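# Shared fixtures, built once per test session. The noise-free cohort is the
# parameter-recovery workhorse: 4 subjects, 150 s each, deterministic
# PPG -> ABP map, so downstream models can be validated against ground truth.

.fixture_env <- new.env()

noise_free_split <- function() {
  if (is.null(.fixture_env$split)) {
    cfg <- synth_config(duration_s = 150, noise_sd_ppg = 0, noise_sd_abp = 0,
                        seed = 3)
    ws <- segment_cohort(generate_cohort(4, cfg))
    ws <- quality_filter(range_filter(ws))
    .fixture_env$split <- split_windows(clean_windows(ws), 0.85, seed = 2)
  }
  .fixture_env$split
}

# scaled-down architectures for fast structural/training tests
tiny_spec <- function(skips = FALSE) {
  dcae_spec(c(8L, 16L), kernel_size = if (skips) 3L else 5L,
            skip_connections = skips, input_len = 640)
}

quick_config <- function(epochs = 3, seed = 1) {
  train_config(epochs = epochs, batch_size = 8, seed = seed)
}

# constant-pressure windows with optional spikes, for filter fixtures
flat_window_set <- function(n, value = 100, wlen = 640, pulse = 20) {
  # a small sawtooth gives each window realistic pulse pressure
  base <- value + pulse * (seq_len(wlen) %% 80) / 80
  ppg <- matrix(rep(sin(seq_len(wlen) / 10), n), nrow = n, byrow = TRUE)
  abp <- matrix(rep(base, n), nrow = n, byrow = TRUE)
  window_set(ppg, abp,
             data.frame(subject_id = rep("T", n), start_sample = seq_len(n)))
}

# Printed 10-fold CV correlation table (SBP, DBP, waveform for each family),
# used as worked-example input for the summary/selection arithmetic.
published_cv_correlations <- function() {
  folds <- 1:10
  ldcae_sbp <- c(0.956, 0.960, 0.962, 0.958, 0.954, 0.951, 0.956, 0.959,
                 0.957, 0.958)
  udcae_sbp <- c(0.958, 0.961, 0.965, 0.969, 0.964, 0.960, 0.957, 0.964,
                 0.963, 0.968)
  ldcae_dbp <- c(0.958, 0.954, 0.951, 0.962, 0.963, 0.959, 0.947, 0.949,
                 0.947, 0.963)
  udcae_dbp <- c(0.953, 0.942, 0.941, 0.953, 0.962, 0.956, 0.951, 0.956,
                 0.946, 0.947)
  ldcae_wf <- c(0.968, 0.969, 0.968, 0.968, 0.966, 0.966, 0.967, 0.968,
                0.966, 0.967)
  udcae_wf <- c(0.974, 0.974, 0.975, 0.976, 0.975, 0.974, 0.973, 0.976,
                0.975, 0.975)
  rbind(
    data.frame(fold = folds, family = "ldcae", sbp_r = ldcae_sbp,
               dbp_r = ldcae_dbp, waveform_r = ldcae_wf),
    data.frame(fold = folds, family = "udcae", sbp_r = udcae_sbp,
               dbp_r = udcae_dbp, waveform_r = udcae_wf)
  )
}

# Printed per-fold error table columns used in summary arithmetic checks.
published_ldcae_sbp_rmse <- function() {
  c(4.69, 4.63, 4.91, 5.19, 5.11, 6.48, 5.02, 4.88, 4.63, 6.39)
}

# Published Bland-Altman rows: mean and SD of differences plus printed limits.
published_bland_altman <- function() {
  data.frame(
    method = rep(c("LDCAE", "UDCAE", "GDCAE"), each = 2),
    series = rep(c("sbp", "dbp"), 3),
    mean_diff = c(-2.274, -0.468, -0.686, 1.099, -1.659, 0.665),
    sd_diff = c(4.661, 2.717, 3.790, 3.057, 2.978, 2.030),
    lower = c(-11.410, -5.793, -8.114, -4.893, -7.496, -3.314),
    upper = c(6.862, 4.857, 6.742, 7.091, 4.178, 4.644)
  )
}

# ten toy candidate models as prediction tables over shared reference windows:
# a few close to truth, the rest increasingly corrupted
toy_candidates <- function(seed = 11, n = 40, len = 640, m = 10) {
  withr::with_seed(seed, {
    t <- seq_len(len) / 64
    ref <- t(sapply(seq_len(n), function(i) {
      90 + 20 * sin(i / 3) + 25 * abs(sin(pi * t * (1 + 0.02 * i)))
    }))
    stack <- array(0, dim = c(n, len, m))
    for (j in seq_len(m)) {
      noise_sd <- c(0.5, 1, 2, 4, 6, 8, 10, 14, 18, 25)[j]
      bias <- rnorm(n, 0, noise_sd / 4)
      stack[, , j] <- ref + matrix(rnorm(n * len, 0, noise_sd), n) + bias
    }
    list(stack = stack, ref = ref)
  })
}
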