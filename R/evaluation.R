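#' Scoring-power statistics
#'
#' The four statistics used to summarise how well a scoring function
#' reproduces measured binding affinities on a set of complexes:
#' Pearson's correlation `Rp`, Spearman's rank correlation `Rs`, the
#' standard deviation `SD` of errors about the least-squares line of
#' measured on predicted affinity, and the root-mean-square error `RMSE`.
#' Degenerate inputs (constant vectors, too few points) raise classed
#' errors rather than returning `NaN`, so pipelines fail loudly.
#'
#' @param y Measured binding affinities (-log Kd / -log Ki units).
#' @param yhat Predicted affinities, same length.
#' @name scoring-power
NULL

check_metric_input <- function(y, yhat, min_n = 3) {
  if (length(y) != length(yhat)) {
    stop_usage("`y` and `yhat` must have the same length.")
  }
  if (length(y) < min_n) {
    stop_usage(paste0("Need at least ", min_n, " observations."))
  }
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop_data("Non-finite values in `y` or `yhat`.")
  }
}

#' @rdname scoring-power
#' @return `pearson_r()`: Pearson's correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (sd(y) == 0 || sd(yhat) == 0) {
    stop_numeric("Pearson correlation undefined for a constant vector.")
  }
  cor(yhat, y)
}

#' @rdname scoring-power
#' @return `spearman_r()`: Spearman's rank correlation (average ranks for
#'   ties; without ties this equals the classical
#'   `1 - 6 * sum(d^2) / (n (n^2 - 1))` rank-difference form).
#' @export
spearman_r <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (length(unique(y)) == 1 || length(unique(yhat)) == 1) {
    stop_numeric("Spearman correlation undefined for an all-tied vector.")
  }
  cor(yhat, y, method = "spearman")
}

#' @rdname scoring-power
#' @return `sd_of_errors()`: residual standard deviation about the fitted
#'   line `y = b0 + b1 * yhat`, with the `n - 2` denominator.
#' @export
sd_of_errors <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (sd(yhat) == 0) {
    stop_numeric("SD of errors undefined: predictions are constant.")
  }
  fit <- lm(y ~ yhat)
  sqrt(sum(fit$residuals^2) / (length(y) - 2))
}

#' @rdname scoring-power
#' @return `rmse()`: root-mean-square error `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  check_metric_input(y, yhat, min_n = 1)
  sqrt(mean((y - yhat)^2))
}

#' Build a scoring report for one model on one dataset
#'
#' Assembles the four scoring-power statistics into a one-row tibble using
#' the `"Model::Features"` labelling convention (for example
#' `"BgN-Score::XARG"`).
#'
#' @param model_label Label of the (model, feature-combination) pair.
#' @param y Measured affinities.
#' @param yhat Predicted affinities.
#' @param rmse_train Optional training-set (out-of-sample validation) RMSE
#'   to carry alongside the test statistics.
#' @return A tibble of class `score_report` with columns `model`, `n`,
#'   `rp`, `rs`, `sd`, `rmse_test`, `rmse_train`.
#' @export
#' @examples
#' score_report("SNN-Score::X", c(5, 6, 7, 8), c(5.1, 6.2, 6.8, 8.1))
score_report <- function(model_label, y, yhat, rmse_train = NULL) {
  out <- tibble::tibble(model = as.character(model_label),
                        n = length(y),
                        rp = pearson_r(y, yhat),
                        rs = spearman_r(y, yhat),
                        sd = sd_of_errors(y, yhat),
                        rmse_test = rmse(y, yhat),
                        rmse_train = rmse_train %||% NA_real_)
  class(out) <- c("score_report", class(out))
  out
}

#' Combine scoring reports into a ranked table
#'
#' @param ... `score_report` rows (or data frames of them).
#' @return One tibble sorted by decreasing Pearson correlation.
#' @export
report_table <- function(...) {
  out <- dplyr::bind_rows(...)
  out <- dplyr::arrange(out, dplyr::desc(.data$rp))
  class(out) <- unique(c("score_report", class(out)))
  out
}

#' Write a scoring report to disk
#'
#' @param report A `score_report` (or any data frame of report rows).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(as.data.frame(report), path, progress = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Predicted-versus-measured scatter plot
#'
#' @param data A feature table scored with [augment()] (columns `affinity`
#'   and `.pred`), or any data frame with those columns.
#' @param label Optional model label for the title.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_predictions <- function(data, label = NULL) {
  if (!all(c("affinity", ".pred") %in% names(data))) {
    stop_usage("`data` needs `affinity` and `.pred` columns (see augment()).")
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$affinity, y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "measured affinity (-log K)",
                  y = "predicted affinity (-log K)",
                  title = label) +
    ggplot2::theme_minimal()
}
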