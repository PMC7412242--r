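#' Leave-testing-out cross-validation
#'
#' Runs k folds per model family against one frozen test set. Each fold
#' re-randomizes only the training side -- weight initialization, the
#' validation carve used for checkpoint monitoring, and the shuffling order
#' all derive from a fold-specific seed -- while training-set membership and
#' the test windows are identical across folds. Every trained model is
#' evaluated on the same frozen test set.
#'
#' @param split a \code{dataset_split} with the frozen test set.
#' @param k number of folds (>= 2); 10 at full scale.
#' @param families character vector among \code{c("ldcae", "udcae")}.
#' @param config a [train_config()].
#' @param specs optional named list of \code{dcae_spec}s per family
#'   (scaled-down architectures for quick runs); defaults to the canonical
#'   family specs.
#' @param seed master seed; per-fold seeds are derived from it.
#' @return an object of class \code{cv_results}: a list of fold results,
#'   each with \code{fold_id}, \code{family}, \code{model}, \code{metrics}
#'   (an [evaluate_predictions()] bundle on the frozen test set).
#' @export
run_cv <- function(split, k = 10, families = c("ldcae", "udcae"),
                   config = train_config(), specs = NULL, seed = config$seed) {
  if (k < 2) stop("invalid config: k must be >= 2", call. = FALSE)
  families <- match.arg(families, c("ldcae", "udcae"), several.ok = TRUE)
  if (is.null(specs))
    specs <- list(ldcae = ldcae_spec(), udcae = udcae_spec())
  test_ws <- clean_windows(split$test)
  results <- list()
  for (fold in seq_len(k)) {
    for (fam in families) {
      fseed <- as.integer((seed + 1009L * fold +
                             match(fam, c("ldcae", "udcae"))) %%
                            .Machine$integer.max)
      cfg <- config
      cfg$seed <- fseed
      model <- build_model(specs[[fam]], seed = fseed)
      model <- train_model(model, split, cfg)
      pred <- predict(model, test_ws$ppg)
      metrics <- evaluate_predictions(pred, test_ws$abp)
      results[[length(results) + 1]] <-
        list(fold_id = fold, family = fam, model = model, metrics = metrics,
             predictions = pred)
    }
  }
  structure(results, class = "cv_results",
            test_windows = test_ws, k = k, families = families)
}

#' Per-fold metric table from cross-validation results
#'
#' @param results a \code{cv_results} object.
#' @return long-format data frame with one row per (fold, family):
#'   correlations and errors of SBP, DBP and the pooled waveform.
#' @export
cv_metrics_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    data.frame(fold = r$fold_id, family = r$family,
               sbp_r = m$sbp$r, dbp_r = m$dbp$r, waveform_r = m$waveform$r,
               sbp_rmse = m$sbp$rmse, sbp_mae = m$sbp$mae,
               dbp_rmse = m$dbp$rmse, dbp_mae = m$dbp$mae,
               waveform_rmse = m$waveform$rmse,
               waveform_mae = m$waveform$mae)
  }))
}

#' Summarize cross-validation metrics
#'
#' Produces the familiar CV summary layout: one wide correlation table with
#' a per-fold row average over all available correlation columns
#' (SBP/DBP/waveform for each family), one wide error table, and column
#' means and sample (n-1) standard deviations for both.
#'
#' @param x a \code{cv_results} object, or a long-format data frame with
#'   columns \code{fold}, \code{family} and any of \code{sbp_r},
#'   \code{dbp_r}, \code{waveform_r}, \code{sbp_rmse}, \code{sbp_mae},
#'   \code{dbp_rmse}, \code{dbp_mae}.
#' @return an object of class \code{cv_summary}: list with
#'   \code{correlations} (wide, incl. \code{average} column),
#'   \code{errors}, \code{correlation_means}, \code{correlation_sds},
#'   \code{error_means}, \code{error_sds}.
#' @export
summarize_cv <- function(x) {
  tab <- if (inherits(x, "cv_results")) cv_metrics_table(x) else x
  if (length(unique(tab$fold)) < 2)
    stop("need at least 2 folds to summarize", call. = FALSE)
  fams <- unique(tab$family)
  folds <- sort(unique(tab$fold))
  widen <- function(cols) {
    out <- data.frame(fold = folds)
    for (cl in cols) {
      if (!cl %in% names(tab)) next
      for (fam in fams) {
        v <- tab[[cl]][match(paste(folds, fam),
                             paste(tab$fold, tab$family))]
        out[[paste(fam, cl, sep = "_")]] <- v
      }
    }
    out
  }
  cors <- widen(c("sbp_r", "dbp_r", "waveform_r"))
  rcols <- setdiff(names(cors), "fold")
  cors$average <- rowMeans(cors[, rcols, drop = FALSE])
  errs <- widen(c("sbp_rmse", "sbp_mae", "dbp_rmse", "dbp_mae",
                  "waveform_rmse", "waveform_mae"))
  colstats <- function(df) {
    num <- df[setdiff(names(df), "fold")]
    list(means = vapply(num, mean, 0), sds = vapply(num, sd, 0))
  }
  cs <- colstats(cors)
  es <- colstats(errs)
  structure(list(correlations = cors, errors = errs,
                 correlation_means = cs$means, correlation_sds = cs$sds,
                 error_means = es$means, error_sds = es$sds),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("<cv_summary>\ncorrelations:\n")
  print(round(x$correlations, 4))
  cat("errors:\n")
  print(round(x$errors, 3))
  invisible(x)
}

#' Select the best single cross-validation fold
#'
#' The fold whose row average over all per-family SBP/DBP/waveform
#' correlations is highest; ties break toward the lowest fold id.
#'
#' @param summary a \code{cv_summary}.
#' @return the winning fold id (integer).
#' @export
select_best <- function(summary) {
  cors <- summary$correlations
  as.integer(cors$fold[which.max(cors$average)])
}
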