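#' End-to-end pipeline configuration
#'
#' Nested configuration for the full simulate -> preprocess -> cross-validate
#' -> ensemble -> report pipeline. Every stage seed is derived
#' deterministically from \code{master_seed}, so partial re-runs are
#' consistent.
#'
#' @param synth a [synth_config()] for the cohort generator.
#' @param n_subjects cohort size.
#' @param window_s window length, seconds.
#' @param range_lo,range_hi ABP gate in mmHg.
#' @param train_fraction train share of the window-level split.
#' @param train a [train_config()].
#' @param k number of CV folds.
#' @param families model families to cross-validate.
#' @param specs optional per-family \code{dcae_spec} overrides.
#' @param ga a [ga_config()].
#' @param master_seed integer master seed fanned out to all stages.
#' @param out_dir optional directory for CSV/JSON reports.
#' @export
pipeline_config <- function(synth = synth_config(), n_subjects = 18,
                            window_s = 5, range_lo = 10, range_hi = 250,
                            train_fraction = 0.85,
                            train = train_config(), k = 10,
                            families = c("ldcae", "udcae"), specs = NULL,
                            ga = ga_config(), master_seed = 1L,
                            out_dir = NULL) {
  structure(list(synth = synth, n_subjects = n_subjects, window_s = window_s,
                 range_lo = range_lo, range_hi = range_hi,
                 train_fraction = train_fraction, train = train, k = k,
                 families = families, specs = specs, ga = ga,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_seed <- function(master, stage) {
  as.integer((master * 131L + stage * 2654435L) %% .Machine$integer.max)
}

#' Run the full estimation pipeline
#'
#' Generates the synthetic cohort, segments and filters windows, splits them
#' 85/15 at window level, runs leave-testing-out cross-validation for each
#' family, selects the best single fold, evolves the genetic-algorithm
#' ensemble on the frozen test set, and evaluates best-LDCAE, best-UDCAE and
#' the ensemble side by side. If \code{out_dir} is set, CSV tables (CV
#' correlations/errors, model comparison, Bland-Altman, GA convergence) and
#' a JSON manifest of seeds and counts are written.
#'
#' @param config a [pipeline_config()].
#' @return list with \code{split}, \code{cv}, \code{summary},
#'   \code{best_fold}, \code{ga}, \code{comparison}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  syn <- config$synth
  syn$seed <- stage_seed(config$master_seed, 1L)
  records <- generate_cohort(config$n_subjects, syn)
  ws <- segment_cohort(records, window_s = config$window_s)
  n_total <- n_windows(ws)
  ws <- range_filter(ws, config$range_lo, config$range_hi)
  ws <- quality_filter(ws)
  flags <- table(factor(ws$quality_flag,
                        c("clean", "rejected_range", "rejected_quality")))
  clean <- clean_windows(ws)
  split <- split_windows(clean, config$train_fraction,
                         seed = stage_seed(config$master_seed, 2L))
  tcfg <- config$train
  cv <- run_cv(split, k = config$k, families = config$families,
               config = tcfg, specs = config$specs,
               seed = stage_seed(config$master_seed, 3L))
  summ <- summarize_cv(cv)
  best_fold <- select_best(summ)

  test_ws <- clean_windows(split$test)
  fin <- fitness_input(cv, test_ws$ppg, test_ws$abp)
  gcfg <- config$ga
  gcfg$seed <- stage_seed(config$master_seed, 4L)
  ga <- evolve_ga(fin, gcfg)

  per_model <- lapply(cv, function(r) r$metrics)
  single_fit <- vapply(seq_along(cv), function(i)
    ga_fitness(replace(integer(length(cv)), i, 1L), fin), 0)
  best_single <- which.max(single_fit)

  comparison <- list()
  for (fam in config$families) {
    idx <- which(vapply(cv, function(r)
      r$family == fam && r$fold_id == best_fold, TRUE))
    m <- cv[[idx]]$metrics
    comparison[[toupper(fam)]] <- comparison_row(m)
  }
  ens_pred <- apply(fin$pred_stack[, , ga$selected, drop = FALSE], c(1, 2),
                    mean)
  ens_m <- evaluate_predictions(ens_pred, test_ws$abp)
  comparison$GDCAE <- comparison_row(ens_m)
  comparison <- do.call(rbind, c(lapply(names(comparison), function(nm)
    cbind(method = nm, comparison[[nm]])), list(make.row.names = FALSE)))

  manifest <- list(master_seed = config$master_seed,
                   n_subjects = config$n_subjects,
                   windows_total = n_total,
                   windows_clean = as.integer(flags[["clean"]]),
                   windows_rejected_range =
                     as.integer(flags[["rejected_range"]]),
                   windows_rejected_quality =
                     as.integer(flags[["rejected_quality"]]),
                   n_train = n_windows(split$train),
                   n_test = n_windows(split$test),
                   k = config$k, families = config$families,
                   epochs = config$train$epochs,
                   generations = config$ga$generations,
                   ga_selected = ga$selected,
                   best_fold = best_fold,
                   best_single_model = fin$model_ids[best_single],
                   best_single_fitness = single_fit[best_single],
                   gdcae_fitness = ga$best_fitness)

  out <- list(split = split, cv = cv, summary = summ, best_fold = best_fold,
              ga = ga, fitness_input = fin, comparison = comparison,
              bland_altman = ens_m$bland_altman, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_report(out, config$out_dir)
  out
}

comparison_row <- function(m) {
  data.frame(waveform_r = m$waveform$r, sbp_r = m$sbp$r, dbp_r = m$dbp$r,
             waveform_rmse = m$waveform$rmse, waveform_mae = m$waveform$mae,
             sbp_rmse = m$sbp$rmse, sbp_mae = m$sbp$mae,
             dbp_rmse = m$dbp$rmse, dbp_mae = m$dbp$mae)
}

write_pipeline_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$summary$correlations,
            file.path(dir, "cv_correlations.csv"), row.names = FALSE)
  write.csv(res$summary$errors, file.path(dir, "cv_errors.csv"),
            row.names = FALSE)
  write.csv(res$comparison, file.path(dir, "model_comparison.csv"),
            row.names = FALSE)
  ba <- do.call(rbind, lapply(names(res$bland_altman), function(nm) {
    b <- res$bland_altman[[nm]]
    data.frame(series = nm, mean_diff = b$mean_diff, sd_diff = b$sd_diff,
               lower_loa = b$lower_loa, upper_loa = b$upper_loa)
  }))
  write.csv(ba, file.path(dir, "bland_altman.csv"), row.names = FALSE)
  write.csv(data.frame(generation = seq_along(res$ga$trace),
                       best_fitness = res$ga$trace),
            file.path(dir, "ga_convergence.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Small frozen fixtures for fast unit tests
#'
#' Generates, deterministically from \code{seed}: a 60-s synthetic record, a
#' 10-window batch, and three toy "models" given as fixed prediction tables
#' over the batch (used to exercise ensemble fitness without training).
#'
#' @param seed integer seed.
#' @return list with \code{record}, \code{batch} (a \code{window_set}),
#'   \code{pred_tables} (n x 640 x 3 array), \code{ref_abp}.
#' @export
make_fixtures <- function(seed = 42L) {
  rec <- generate_record(synth_config(duration_s = 60, noise_sd_ppg = 0,
                                      noise_sd_abp = 0, seed = seed))
  batch <- segment_windows(rec)[1:10]
  stack <- withr::with_seed(seed, {
    s <- array(0, dim = c(10, ncol(batch$abp), 3))
    s[, , 1] <- batch$abp                                   # exact model
    s[, , 2] <- batch$abp + rnorm(length(batch$abp), 0, 3)  # noisy model
    s[, , 3] <- batch$abp + 5                               # biased model
    s
  })
  list(record = rec, batch = batch, pred_tables = stack, ref_abp = batch$abp)
}
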