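#' Window sets: batches of paired 5-s PPG/ABP windows
#'
#' A \code{window_set} holds aligned PPG and ABP windows as \code{(N, L)}
#' matrices (one row per window, L = window seconds x sampling rate, 640 at
#' the defaults) together with their provenance (subject id, start sample)
#' and a per-window quality flag in \code{{"clean", "rejected_range",
#' "rejected_quality"}}.
#'
#' @param ppg,abp numeric matrices of equal dimension, one window per row.
#' @param source data frame with columns \code{subject_id},
#'   \code{start_sample}.
#' @param quality_flag character vector, one entry per window.
#' @return an object of class \code{window_set}.
#' @export
window_set <- function(ppg, abp, source, quality_flag = NULL) {
  stopifnot(is.matrix(ppg), is.matrix(abp), all(dim(ppg) == dim(abp)),
            nrow(source) == nrow(ppg))
  if (is.null(quality_flag)) quality_flag <- rep("clean", nrow(ppg))
  structure(list(ppg = ppg, abp = abp, source = source,
                 quality_flag = quality_flag), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  tab <- table(factor(x$quality_flag,
                      c("clean", "rejected_range", "rejected_quality")))
  cat(sprintf("<window_set> %d windows x %d samples (%d clean, %d rejected_range, %d rejected_quality)\n",
              nrow(x$ppg), ncol(x$ppg), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a \code{window_set}.
#' @export
n_windows <- function(ws) nrow(ws$ppg)

#' Subset a window set by window index
#' @param x a \code{window_set}.
#' @param i integer or logical index over windows.
#' @param ... unused.
#' @export
`[.window_set` <- function(x, i, ...) {
  window_set(x$ppg[i, , drop = FALSE], x$abp[i, , drop = FALSE],
             x$source[i, , drop = FALSE], x$quality_flag[i])
}

#' Concatenate window sets (e.g. across the subjects of a cohort)
#' @param ... \code{window_set}s with matching window length.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) sets <- sets[[1]]
  window_set(do.call(rbind, lapply(sets, `[[`, "ppg")),
             do.call(rbind, lapply(sets, `[[`, "abp")),
             do.call(rbind, lapply(sets, `[[`, "source")),
             unlist(lapply(sets, `[[`, "quality_flag")))
}

#' Segment a record into non-overlapping fixed-length window pairs
#'
#' Consecutive, non-overlapping windows of \code{window_s * fs} samples are
#' cut from the start of the record; a trailing remainder shorter than one
#' window is dropped. A record shorter than one window yields an empty set.
#'
#' @param record a \code{waveform_record}.
#' @param window_s window length in seconds (5 by default).
#' @param fs sampling rate; defaults to the record's.
#' @return a \code{window_set} with all flags \code{"clean"}.
#' @export
segment_windows <- function(record, window_s = 5, fs = record$fs) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  wlen <- round(window_s * fs)
  n <- length(record$ppg)
  nw <- floor(n / wlen)
  if (nw < 1) {
    return(window_set(matrix(numeric(), 0, wlen), matrix(numeric(), 0, wlen),
                      data.frame(subject_id = character(),
                                 start_sample = integer())))
  }
  used <- nw * wlen
  ppg <- matrix(record$ppg[seq_len(used)], nrow = nw, byrow = TRUE)
  abp <- matrix(record$abp[seq_len(used)], nrow = nw, byrow = TRUE)
  src <- data.frame(subject_id = rep(record$subject_id, nw),
                    start_sample = (seq_len(nw) - 1L) * wlen + 1L)
  window_set(ppg, abp, src)
}

#' Segment every record of a cohort into one pooled window set
#' @param records list of \code{waveform_record}s.
#' @inheritParams segment_windows
#' @export
segment_cohort <- function(records, window_s = 5) {
  bind_window_sets(lapply(records, segment_windows, window_s = window_s))
}

#' Physiological range filter on the ABP channel
#'
#' Windows whose ABP channel has any sample outside \code{[lo, hi]} mmHg are
#' flagged \code{"rejected_range"}. Range rejection takes precedence over
#' quality rejection regardless of filter order, so
#' \code{range_filter(quality_filter(ws))} and
#' \code{quality_filter(range_filter(ws))} assign identical flags.
#'
#' @param ws a \code{window_set}.
#' @param lo,hi bounds in mmHg (10 and 250 by default).
#' @return the window set with updated flags; use [clean_windows()] to keep
#'   only unflagged windows. Kept/rejected counts are attached as attribute
#'   \code{"counts"}.
#' @export
range_filter <- function(ws, lo = 10, hi = 250) {
  if (lo >= hi) stop("lo must be below hi", call. = FALSE)
  bad <- apply(ws$abp, 1, function(r) any(r < lo | r > hi))
  ws$quality_flag[bad] <- "rejected_range"
  attr(ws, "counts") <- c(kept = sum(!bad), rejected = sum(bad))
  ws
}

#' Automated signal-quality filter
#'
#' A reproducible surrogate for by-eye quality screening: a window is flagged
#' \code{"rejected_quality"} if its ABP variance is below \code{var_eps}
#' (flatline), its PPG variance is below \code{var_eps} (flatline sensor), or
#' its pulse pressure (window max minus min) falls outside
#' \code{[pp_min, pp_max]} mmHg. Windows already flagged
#' \code{"rejected_range"} keep that flag.
#'
#' @param ws a \code{window_set}.
#' @param var_eps variance floor for the flatline test.
#' @param pp_min,pp_max plausible pulse-pressure band in mmHg.
#' @return the window set with updated flags and a \code{"counts"} attribute.
#' @export
quality_filter <- function(ws, var_eps = 1e-6, pp_min = 5, pp_max = 150) {
  v_abp <- apply(ws$abp, 1, var)
  v_ppg <- apply(ws$ppg, 1, var)
  pp <- apply(ws$abp, 1, function(r) max(r) - min(r))
  bad <- v_abp < var_eps | v_ppg < var_eps | pp < pp_min | pp > pp_max
  set <- bad & ws$quality_flag != "rejected_range"
  ws$quality_flag[set] <- "rejected_quality"
  attr(ws, "counts") <- c(kept = sum(!bad), rejected = sum(bad))
  ws
}

#' Keep only windows flagged clean
#' @param ws a \code{window_set}.
#' @export
clean_windows <- function(ws) ws[ws$quality_flag == "clean"]

#' Random train/test split of a window set
#'
#' Reproducible window-level partition: \code{floor(n * train_fraction)}
#' windows go to training, the remainder to the frozen test set that all
#' downstream cross-validation folds share.
#'
#' @param ws a \code{window_set} (usually already cleaned).
#' @param train_fraction proportion in (0, 1); 0.85 by default.
#' @param seed integer seed for the permutation.
#' @return an object of class \code{dataset_split}: list with
#'   \code{train}, \code{test} (window sets), \code{split_seed},
#'   \code{train_fraction}.
#' @export
split_windows <- function(ws, train_fraction = 0.85, seed = 1L) {
  n <- n_windows(ws)
  if (n < 2) stop("need at least 2 windows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("invalid config: train_fraction must lie in (0, 1)", call. = FALSE)
  n_train <- floor(n * train_fraction)
  perm <- withr::with_seed(seed, sample.int(n))
  structure(list(train = ws[sort(perm[seq_len(n_train)])],
                 test = ws[sort(perm[seq.int(n_train + 1, n)])],
                 split_seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test windows (fraction %.2f, seed %d)\n",
              n_windows(x$train), n_windows(x$test), x$train_fraction,
              x$split_seed))
  invisible(x)
}

#' Fit and apply the PPG input normalizer
#'
#' The PPG channel is scaled to \code{[0, 1]} by the global min/max of the
#' training windows; the ABP target stays in mmHg so model outputs remain
#' interpretable. The transform is exactly invertible via
#' \code{denormalize_ppg}.
#'
#' @param train_ws training \code{window_set} the statistics are fitted on.
#' @return \code{fit_normalizer} returns a list with \code{ppg_min},
#'   \code{ppg_max}.
#' @export
fit_normalizer <- function(train_ws) {
  lo <- min(train_ws$ppg)
  hi <- max(train_ws$ppg)
  if (hi <= lo) stop("degenerate normalization: max equals min", call. = FALSE)
  structure(list(ppg_min = lo, ppg_max = hi), class = "ppg_normalizer")
}

#' @rdname fit_normalizer
#' @param ws window set (or PPG matrix) to scale.
#' @param stats a fitted normalizer.
#' @export
normalize_windows <- function(ws, stats) {
  sc <- function(m) (m - stats$ppg_min) / (stats$ppg_max - stats$ppg_min)
  if (is.matrix(ws)) return(sc(ws))
  ws$ppg <- sc(ws$ppg)
  ws
}

#' @rdname fit_normalizer
#' @param m normalized PPG matrix.
#' @export
denormalize_ppg <- function(m, stats) {
  m * (stats$ppg_max - stats$ppg_min) + stats$ppg_min
}
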