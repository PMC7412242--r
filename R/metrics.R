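#' Agreement metrics between reference and estimated pressures
#'
#' \code{mae} is the mean absolute error \eqn{\frac{1}{n}\sum |x_i - y_i|},
#' \code{rmse} the root mean squared error
#' \eqn{\sqrt{\frac{1}{n}\sum (x_i - y_i)^2}}, and \code{pearson_r} the
#' product-moment correlation coefficient. \code{x} is the reference series
#' (gold standard), \code{y} the estimate; both in mmHg for pressure series.
#' \code{pearson_r} returns values in \eqn{[-1, 1]}.
#'
#' @param x numeric reference series.
#' @param y numeric estimated series of the same length.
#' @return a single number.
#' @export
mae <- function(x, y) {
  check_paired(x, y)
  mean(abs(x - y))
}

#' @rdname mae
#' @export
rmse <- function(x, y) {
  check_paired(x, y)
  sqrt(mean((x - y)^2))
}

#' @rdname mae
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y, min_n = 2)
  xc <- x - mean(x)
  yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den <= 0)
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  sum(xc * yc) / den
}

check_paired <- function(x, y, min_n = 1) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  invisible(NULL)
}

#' Extract systolic and diastolic pressure from ABP windows
#'
#' The maximum of a 5-s ABP segment is taken as SBP, the minimum as DBP --
#' the operational definition used throughout this package (pressures do not
#' change appreciably within five seconds).
#'
#' @param abp a numeric vector (one window) or matrix (one window per row).
#' @return a data frame with columns \code{sbp}, \code{dbp} (mmHg), one row
#'   per window.
#' @examples
#' extract_sbp_dbp(c(80, 120, 80))  # sbp 120, dbp 80
#' @export
extract_sbp_dbp <- function(abp) {
  if (is.matrix(abp)) {
    if (ncol(abp) < 1) stop("empty window", call. = FALSE)
    data.frame(sbp = apply(abp, 1, max), dbp = apply(abp, 1, min))
  } else {
    if (length(abp) < 1) stop("empty window", call. = FALSE)
    data.frame(sbp = max(abp), dbp = min(abp))
  }
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as estimate minus reference (\code{y - x}); the
#' standard deviation uses the sample (n-1) convention, and the limits of
#' agreement are \code{mean_diff +/- 1.96 * sd_diff}.
#'
#' @param x reference series (mmHg).
#' @param y estimated series (mmHg).
#' @param sign either \code{"estimate-reference"} (default) or
#'   \code{"reference-estimate"}.
#' @return list with \code{mean_diff}, \code{sd_diff}, \code{lower_loa},
#'   \code{upper_loa}, \code{n}.
#' @export
bland_altman <- function(x, y, sign = c("estimate-reference",
                                        "reference-estimate")) {
  check_paired(x, y, min_n = 2)
  sign <- match.arg(sign)
  d <- if (sign == "estimate-reference") y - x else x - y
  m <- mean(d)
  s <- sd(d)
  c(list(mean_diff = m, sd_diff = s), loa_limits(m, s), list(n = length(d)))
}

#' Limits of agreement from a printed mean and SD of differences
#' @param mean_diff mean difference, mmHg.
#' @param sd_diff standard deviation of the differences, mmHg.
#' @return list with \code{lower_loa}, \code{upper_loa}.
#' @export
loa_limits <- function(mean_diff, sd_diff) {
  list(lower_loa = mean_diff - 1.96 * sd_diff,
       upper_loa = mean_diff + 1.96 * sd_diff)
}

#' Full evaluation of predicted ABP windows against reference windows
#'
#' Computes waveform-level MAE/RMSE/Pearson r pooled over all samples of all
#' windows, per-window SBP- and DBP-level MAE/RMSE/r, Bland-Altman statistics
#' for SBP and DBP, and error histograms.
#'
#' @param pred matrix of predicted ABP windows (mmHg), one per row.
#' @param ref matrix of reference ABP windows, same dimension.
#' @return list with elements \code{waveform}, \code{sbp}, \code{dbp} (each
#'   a list \code{mae}, \code{rmse}, \code{r}), \code{bland_altman} (lists
#'   for \code{sbp} and \code{dbp}) and \code{error_hist}.
#' @export
evaluate_predictions <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref)))
    stop("prediction and reference sets are misaligned", call. = FALSE)
  wf_x <- as.numeric(t(ref))
  wf_y <- as.numeric(t(pred))
  bp_ref <- extract_sbp_dbp(ref)
  bp_est <- extract_sbp_dbp(pred)
  bundle <- function(x, y) list(mae = mae(x, y), rmse = rmse(x, y),
                                r = pearson_r(x, y))
  list(
    waveform = bundle(wf_x, wf_y),
    sbp = bundle(bp_ref$sbp, bp_est$sbp),
    dbp = bundle(bp_ref$dbp, bp_est$dbp),
    bland_altman = list(sbp = bland_altman(bp_ref$sbp, bp_est$sbp),
                        dbp = bland_altman(bp_ref$dbp, bp_est$dbp)),
    error_hist = list(sbp = graphics::hist(bp_est$sbp - bp_ref$sbp,
                                           plot = FALSE),
                      dbp = graphics::hist(bp_est$dbp - bp_ref$dbp,
                                           plot = FALSE)),
    n_windows = nrow(ref)
  )
}
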