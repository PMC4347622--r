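#' Fit a boosted ensemble of networks (BsN-Score)
#'
#' Builds a stage-wise additive model of `L` single-hidden-layer networks.
#' The first network is fit to all training complexes on a random feature
#' subset, and the working residuals are set to `y - nu * f1(x)`. Every
#' later stage draws a bootstrap sample of the rows, draws a fresh random
#' feature subset, trains a network on the sampled rows' current residuals,
#' predicts on the full training set, and updates the residuals by
#' subtracting `nu` times those predictions. Every stage, the first
#' included, enters the final model shrunk by `nu`, so the model's total
#' weight is `L * nu`: with the benchmark shrinkage `nu = 0.001` the
#' matching stage count is `L = 3000`, and small `L` with small `nu`
#' systematically under-predicts (a visible consequence of the shrink-all
#' aggregation rule, documented rather than altered).
#'
#' @param data A feature table.
#' @param L Number of boosting stages (benchmark setting 3000).
#' @param subset_size Features per stage, drawn without replacement.
#' @param hidden Hidden neurons per member including the bias unit.
#' @param nu Shrinkage in `(0, 1)` applied to every stage (benchmark 0.001).
#' @param config A [train_config()].
#' @return A `bsn_ensemble`: ordered members, `nu`, and `residual_trace`,
#'   the residual sum of squares on the full training set after each stage.
#' @export
#' @examples
#' sim <- generate_complexes(synthetic_spec(n = 60, seed = 3))
#' ens <- fit_boosting(sim$data, L = 5, subset_size = 5, hidden = 6,
#'                     nu = 0.1, config = train_config(epochs = 50, seed = 1))
#' glance(ens)
fit_boosting <- function(data, L = 3000, subset_size = 10, hidden = 20,
                         nu = 0.001, config = train_config()) {
  validate_feature_table(data)
  if (L < 1) stop_usage("`L` must be >= 1.")
  if (!is.numeric(nu) || nu <= 0 || nu >= 1) {
    stop_usage("`nu` must lie strictly between 0 and 1.")
  }
  feats <- feature_cols(data)
  if (subset_size < 1 || subset_size > length(feats)) {
    stop_usage(paste0("`subset_size` must be in 1..", length(feats), "."))
  }
  if (nrow(data) < 2) stop_usage("Need at least 2 training rows.")

  seeds <- member_seeds(config$seed, L)
  n <- nrow(data)
  members <- vector("list", L)
  trace <- numeric(L)
  work <- data
  resid <- data$affinity

  for (l in seq_len(L)) {
    first <- l == 1L
    des <- draw_member_design(seeds[1, l], n, feats, subset_size,
                              bootstrap = !first)
    work_l <- data[des$rows, , drop = FALSE]
    # stage targets: measured affinities for stage 1, the sampled rows'
    # current residuals afterwards (duplicates carry duplicate rows)
    work_l$affinity <- if (first) data$affinity[des$rows] else resid[des$rows]
    members[[l]] <- train_member(work_l, des$features, hidden, config,
                                 seeds[2, l])
    pred_all <- predict(members[[l]], data)
    resid <- if (first) data$affinity - nu * pred_all else resid - nu * pred_all
    if (!all(is.finite(resid))) {
      stop_numeric(paste0("Non-finite residuals at boosting stage ", l, "."))
    }
    trace[l] <- sum(resid^2)
  }
  structure(list(members = members, nu = nu, residual_trace = trace,
                 subset_size = as.integer(subset_size),
                 hidden = as.integer(hidden), config = config,
                 seed = config$seed, n_train = n,
                 train_ids = data$complex_id),
            class = "bsn_ensemble")
}

#' Predict binding affinity with a boosted ensemble
#'
#' The prediction is the shrinkage-weighted sum over all stages,
#' `sum_l nu * f_l(x)`, each stage seeing its own feature subset.
#'
#' @param object A `bsn_ensemble`.
#' @param newdata A feature table containing every feature used by any
#'   stage.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities.
#' @export
predict.bsn_ensemble <- function(object, newdata, ...) {
  pm <- member_prediction_matrix(object$members, newdata)
  if (nrow(as.data.frame(newdata)) == 1) pm <- matrix(pm, nrow = 1)
  object$nu * rowSums(pm)
}

#' @export
print.bsn_ensemble <- function(x, ...) {
  cat("<bsn_ensemble> boosted network scoring function (BsN-Score)\n")
  cat("  stages:", length(x$members), " shrinkage nu:", x$nu,
      " feature subset size:", x$subset_size, "\n")
  cat("  residual RSS: stage 1", format(x$residual_trace[1], digits = 5),
      "-> final", format(x$residual_trace[length(x$residual_trace)],
                         digits = 5), "\n")
  invisible(x)
}

#' @export
tidy.bsn_ensemble <- function(x, ...) {
  tibble::tibble(stage = seq_along(x$residual_trace),
                 rss = x$residual_trace,
                 rmse = sqrt(x$residual_trace / x$n_train),
                 features = lapply(x$members, function(m) m$features))
}

#' @export
glance.bsn_ensemble <- function(x, ...) {
  tibble::tibble(L = length(x$members), nu = x$nu,
                 subset_size = x$subset_size, hidden = x$hidden,
                 lambda = x$config$lambda, n_train = x$n_train,
                 final_rss = x$residual_trace[length(x$residual_trace)],
                 seed = x$seed)
}

#' @export
augment.bsn_ensemble <- function(x, data, ...) {
  pred <- predict(x, data)
  dplyr::mutate(data, .pred = pred, .resid = .data$affinity - pred)
}

#' Residual-trace plot for a boosted ensemble
#'
#' Training root-mean-square residual after each boosting stage.
#'
#' @param object A `bsn_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bsn_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$rmse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "boosting stage", y = "training RMS residual",
                  title = "BsN-Score residual trace") +
    ggplot2::theme_minimal()
}

default_candidate <- function() {
  list(model = "bsn", L = 50, subset_size = 10, hidden = 20, nu = 0.01,
       epochs = 200, lambda = 0.005)
}

fit_candidate <- function(cand, data, seed) {
  cfg <- train_config(epochs = cand$epochs, lambda = cand$lambda, seed = seed)
  p <- length(feature_cols(data))
  switch(cand$model,
         snn = train_network(data, hidden = cand$hidden, config = cfg),
         bgn = fit_bagging(data, L = cand$L,
                           subset_size = min(cand$subset_size, p),
                           hidden = cand$hidden, config = cfg),
         bsn = fit_boosting(data, L = cand$L,
                            subset_size = min(cand$subset_size, p),
                            hidden = cand$hidden, nu = cand$nu, config = cfg),
         stop_usage(paste0("Unknown model type: ", cand$model)))
}

#' Select a configuration by k-fold cross-validation
#'
#' Scores every candidate configuration by its mean held-out RMSE over a
#' `k`-fold partition of the training rows (the validation protocol used for
#' boosted and single-network scoring functions; bagged ensembles use
#' out-of-bag validation instead, see [oob_rmse()]). Ties are broken in
#' favour of the simpler configuration: fewer stages/members, then smaller
#' feature subset.
#'
#' @param data A feature table.
#' @param grid A data frame of candidates with any of the columns `model`
#'   (`"snn"`, `"bgn"`, `"bsn"`), `L`, `subset_size`, `hidden`, `nu`,
#'   `epochs`, `lambda`; missing columns take the defaults
#'   (bsn, L = 50, subset_size = 10, hidden = 20, nu = 0.01, epochs = 200,
#'   lambda = 0.005).
#' @param k Number of folds (benchmark protocol: 10).
#' @param seed Integer seed controlling fold assignment and candidate fits.
#' @return A list with `best` (the winning candidate as a one-row tibble)
#'   and `cv` (per-candidate mean and per-fold RMSE).
#' @export
tune_by_cv <- function(data, grid, k = 10, seed = 1) {
  validate_feature_table(data)
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) stop_usage("`grid` must contain at least one candidate.")
  defaults <- default_candidate()
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  folds <- kfold_indices(nrow(data), k, seed)
  fold_err <- matrix(NA_real_, nrow = nrow(grid), ncol = k)
  for (i in seq_len(nrow(grid))) {
    cand <- as.list(grid[i, ])
    for (j in seq_len(k)) {
      test_rows <- folds[[j]]
      fit <- fit_candidate(cand, data[-test_rows, , drop = FALSE],
                           seed = seed + j)
      pred <- predict(fit, data[test_rows, , drop = FALSE])
      fold_err[i, j] <- rmse(data$affinity[test_rows], pred)
    }
  }
  cv <- dplyr::mutate(grid, cv_rmse = rowMeans(fold_err),
                      fold_rmse = lapply(seq_len(nrow(grid)),
                                         function(i) fold_err[i, ]))
  ord <- order(cv$cv_rmse, cv$L, cv$subset_size)
  list(best = cv[ord[1], setdiff(names(cv), "fold_rmse")], cv = cv)
}
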