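#' Configuration for the synthetic paired PPG/ABP generator
#'
#' Describes one simulated recording: duration, sampling rate, heart-rate
#' statistics, baseline systolic/diastolic pressures, slow sinusoidal blood
#' pressure drift, per-channel additive noise, and an optional contiguous
#' block of artifact-corrupted windows.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (128 by default, matching typical patient
#'   monitor exports).
#' @param hr_mean,hr_sd mean and beat-to-beat standard deviation of heart
#'   rate, beats/min.
#' @param sbp_base,dbp_base baseline systolic and diastolic pressure, mmHg.
#'   Must satisfy \code{10 <= dbp_base < sbp_base <= 250}.
#' @param drift_amplitude amplitude (mmHg) of the slow sinusoidal SBP drift;
#'   DBP drifts in phase at half amplitude so pulse pressure stays positive.
#' @param drift_period_s period of the drift, seconds.
#' @param noise_sd_ppg,noise_sd_abp additive Gaussian noise SD per channel
#'   (a.u. for PPG, mmHg for ABP).
#' @param artifact_fraction proportion in \code{[0,1]} of 5-s windows
#'   corrupted by a contiguous artifact block (flatline or broadband noise).
#' @param seed integer seed; identical configurations produce bit-identical
#'   records.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(duration_s = 300, fs = 128, hr_mean = 75, hr_sd = 3,
                         sbp_base = 120, dbp_base = 80,
                         drift_amplitude = 10, drift_period_s = 60,
                         noise_sd_ppg = 0.01, noise_sd_abp = 1,
                         artifact_fraction = 0, seed = 1L) {
  cfg <- list(duration_s = duration_s, fs = fs, hr_mean = hr_mean,
              hr_sd = hr_sd, sbp_base = sbp_base, dbp_base = dbp_base,
              drift_amplitude = drift_amplitude,
              drift_period_s = drift_period_s,
              noise_sd_ppg = noise_sd_ppg, noise_sd_abp = noise_sd_abp,
              artifact_fraction = artifact_fraction, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stop("invalid config: duration_s must be positive", call. = FALSE)
  if (!is.numeric(cfg$fs) || cfg$fs <= 0)
    stop("invalid config: fs must be positive", call. = FALSE)
  if (cfg$dbp_base >= cfg$sbp_base)
    stop("invalid config: dbp_base must be below sbp_base", call. = FALSE)
  if (cfg$dbp_base < 10 || cfg$sbp_base > 250)
    stop("invalid config: baseline pressures must lie in [10, 250] mmHg",
         call. = FALSE)
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction > 1)
    stop("invalid config: artifact_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$hr_mean <= 0) stop("invalid config: hr_mean must be positive",
                             call. = FALSE)
  invisible(cfg)
}

# two-Gaussian pulse shape on beat phase u in [0,1): systolic peak + dicrotic
# bump; parameters differ per channel so the PPG -> ABP map is a non-trivial
# but deterministic morphological transform
pulse_shape_abp <- function(u) {
  exp(-(u - 0.30)^2 / (2 * 0.09^2)) + 0.35 * exp(-(u - 0.62)^2 / (2 * 0.07^2))
}

pulse_shape_ppg <- function(u) {
  exp(-(u - 0.36)^2 / (2 * 0.11^2)) + 0.50 * exp(-(u - 0.68)^2 / (2 * 0.08^2))
}

#' Generate one synthetic paired PPG/ABP record
#'
#' Beats are laid down with inter-beat intervals drawn from a truncated
#' normal distribution. Each beat contributes a two-Gaussian pulse template
#' (systolic peak plus dicrotic bump) to both channels. The ABP pulse is
#' min-max anchored per beat to span exactly \code{[DBP_t, SBP_t]}, where the
#' per-beat targets follow the configured sinusoidal drift; the PPG channel
#' uses a related template whose baseline tracks DBP and whose amplitude
#' tracks pulse pressure, so the PPG to ABP mapping is deterministic and
#' learnable. Gaussian noise is then added per channel, and an optional
#' contiguous block of 5-s windows is corrupted (flatline or high-amplitude
#' noise) and recorded.
#'
#' @param config a [synth_config()].
#' @param subject_id label stored on the record.
#' @return an object of class \code{waveform_record}: a list with elements
#'   \code{ppg}, \code{abp} (numeric vectors of equal length), \code{fs},
#'   \code{subject_id}, \code{beats} (per-beat ground-truth annotations:
#'   start/end sample, SBP, DBP) and \code{artifacts} (corrupted 5-s window
#'   table, possibly empty).
#' @examples
#' rec <- generate_record(synth_config(duration_s = 30, seed = 7))
#' length(rec$abp)  # 30 * 128
#' @export
generate_record <- function(config, subject_id = "S01") {
  validate_synth_config(config)
  withr::with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    mean_ibi <- 60 / config$hr_mean
    sd_ibi <- 60 * config$hr_sd / config$hr_mean^2
    # draw enough beats to cover the record, truncated away from zero
    n_beats_max <- ceiling(config$duration_s / mean_ibi * 1.6) + 8
    ibi <- pmax(rnorm(n_beats_max, mean_ibi, sd_ibi), 0.3 * mean_ibi)
    starts <- cumsum(c(0, ibi))
    ppg <- numeric(n)
    abp <- numeric(n)
    beats <- list()
    k <- 1L
    for (j in seq_along(ibi)) {
      s0 <- round(starts[j] * fs)          # 0-based sample offset
      s1 <- round(starts[j + 1] * fs) - 1  # inclusive
      if (s0 >= n) break
      idx <- s0:min(s1, n - 1)
      u <- (idx - s0) / (s1 - s0 + 1)
      t_beat <- starts[j]
      w <- 2 * pi * t_beat / config$drift_period_s
      sbp_t <- config$sbp_base + config$drift_amplitude * sin(w)
      dbp_t <- config$dbp_base + 0.5 * config$drift_amplitude * sin(w)
      g <- pulse_shape_abp(u)
      gn <- if (length(g) > 1 && diff(range(g)) > 0)
        (g - min(g)) / (max(g) - min(g)) else rep(0, length(g))
      abp[idx + 1] <- dbp_t + (sbp_t - dbp_t) * gn
      h <- pulse_shape_ppg(u)
      hn <- if (length(h) > 1 && diff(range(h)) > 0)
        (h - min(h)) / (max(h) - min(h)) else rep(0, length(h))
      ppg[idx + 1] <- dbp_t / 200 + (sbp_t - dbp_t) / 60 * hn
      if (s1 <= n - 1) {  # annotate only complete beats
        beats[[k]] <- data.frame(beat = k, start_sample = s0 + 1,
                                 end_sample = s1 + 1, sbp = sbp_t,
                                 dbp = dbp_t)
        k <- k + 1L
      }
    }
    beats <- if (length(beats)) do.call(rbind, beats) else
      data.frame(beat = integer(), start_sample = integer(),
                 end_sample = integer(), sbp = numeric(), dbp = numeric())
    if (config$noise_sd_ppg > 0) ppg <- ppg + rnorm(n, 0, config$noise_sd_ppg)
    if (config$noise_sd_abp > 0) abp <- abp + rnorm(n, 0, config$noise_sd_abp)

    artifacts <- data.frame(window = integer(), start_sample = integer(),
                            end_sample = integer(), type = character())
    wlen <- 5 * fs
    n_win <- floor(n / wlen)
    n_art <- round(config$artifact_fraction * n_win)
    if (n_art > 0) {
      first <- sample.int(n_win - n_art + 1, 1)
      for (wi in first:(first + n_art - 1)) {
        i0 <- (wi - 1) * wlen + 1
        i1 <- wi * wlen
        type <- sample(c("flatline", "noise"), 1)
        if (type == "flatline") {
          abp[i0:i1] <- mean(abp[i0:i1])
          ppg[i0:i1] <- mean(ppg[i0:i1])
        } else {
          abp[i0:i1] <- abp[i0:i1] + rnorm(wlen, 0, 60)
          ppg[i0:i1] <- ppg[i0:i1] + rnorm(wlen, 0, 1)
        }
        artifacts <- rbind(artifacts,
                           data.frame(window = wi, start_sample = i0,
                                      end_sample = i1, type = type))
      }
    }
    structure(list(ppg = ppg, abp = abp, fs = fs, subject_id = subject_id,
                   beats = beats, artifacts = artifacts, config = config),
              class = "waveform_record")
  })
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s: %d samples @ %g Hz (%.1f s), %d annotated beats, %d artifact windows\n",
              x$subject_id, length(x$abp), x$fs, length(x$abp) / x$fs,
              nrow(x$beats), nrow(x$artifacts)))
  invisible(x)
}

# deterministic per-subject config: derived seed plus uniform +/-10% jitter
# on heart rate and baseline pressures
subject_config <- function(config, j) {
  jit <- withr::with_seed(config$seed, {
    m <- matrix(runif(3 * j, 0.9, 1.1), ncol = 3)
    m[j, ]
  })
  cfg <- config
  cfg$hr_mean <- config$hr_mean * jit[1]
  cfg$sbp_base <- min(config$sbp_base * jit[2], 250)
  cfg$dbp_base <- max(config$dbp_base * jit[3], 10)
  if (cfg$dbp_base >= cfg$sbp_base) cfg$dbp_base <- cfg$sbp_base - 20
  cfg$seed <- as.integer((config$seed + 7919 * j) %% .Machine$integer.max)
  cfg
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from \code{config$seed},
#' and subject-level heart rate and baseline pressures are jittered uniformly
#' within ±10% of the configured bases, creating inter-subject variability
#' while staying inside the 10-250 mmHg physiological gate.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config a [synth_config()] giving the population-level parameters.
#' @return list of \code{waveform_record}s with distinct subject ids.
#' @export
generate_cohort <- function(n_subjects, config) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("invalid config: n_subjects must be >= 1", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  lapply(seq_len(n_subjects), function(j) {
    generate_record(subject_config(config, j),
                    subject_id = sprintf("S%02d", j))
  })
}

#' Write / read a waveform record as plain text
#'
#' Each channel goes to a two-column CSV (\code{time_s, value}); sampling
#' rate, subject id, beat annotations and artifact windows go to a JSON
#' sidecar.
#'
#' @param record a \code{waveform_record}.
#' @param dir output directory (created if needed).
#' @return \code{write_record} returns the directory invisibly;
#'   \code{read_record} returns a \code{waveform_record}.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- (seq_along(record$ppg) - 1) / record$fs
  write.csv(data.frame(time_s = t, value = record$ppg),
            file.path(dir, paste0(record$subject_id, "_ppg.csv")),
            row.names = FALSE)
  write.csv(data.frame(time_s = t, value = record$abp),
            file.path(dir, paste0(record$subject_id, "_abp.csv")),
            row.names = FALSE)
  side <- list(fs = record$fs, subject_id = record$subject_id,
               beats = record$beats, artifacts = record$artifacts)
  jsonlite::write_json(side, file.path(dir, paste0(record$subject_id,
                                                   "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_record
#' @param subject_id subject whose files to read back.
#' @export
read_record <- function(dir, subject_id) {
  ppg <- read.csv(file.path(dir, paste0(subject_id, "_ppg.csv")))
  abp <- read.csv(file.path(dir, paste0(subject_id, "_abp.csv")))
  meta <- jsonlite::read_json(file.path(dir, paste0(subject_id,
                                                    "_meta.json")),
                              simplifyVector = TRUE)
  beats <- as.data.frame(meta$beats)
  artifacts <- as.data.frame(meta$artifacts)
  structure(list(ppg = ppg$value, abp = abp$value, fs = meta$fs,
                 subject_id = meta$subject_id, beats = beats,
                 artifacts = artifacts, config = NULL),
            class = "waveform_record")
}
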