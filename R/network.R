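#' Training configuration for a single network
#'
#' Collects the knobs of the regularised network fit. Defaults are the
#' benchmark settings used throughout the package: 3000 training epochs
#' (quasi-Newton iterations), weight decay `lambda = 0.005`, early stop when
#' the penalised fitting criterion falls below `abstol = 1e-4`, and initial
#' weights drawn uniformly from `[-0.7, 0.7]`.
#'
#' @param epochs Maximum number of optimizer iterations (>= 1).
#' @param lambda Weight-decay coefficient (>= 0); multiplies the squared
#'   norm of all weights, biases included, in the fitting criterion.
#' @param abstol Early-stopping threshold on the fitting criterion (> 0).
#' @param init_range Half-width of the symmetric uniform weight
#'   initialisation (> 0).
#' @param seed Integer seed for weight initialisation (and, in ensembles,
#'   the root of all resampling seeds).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 3000, lambda = 0.005, abstol = 1e-4,
                         init_range = 0.7, seed = 1) {
  if (epochs < 1) stop_usage("`epochs` must be >= 1.")
  if (lambda < 0) stop_usage("`lambda` must be >= 0.")
  if (abstol <= 0) stop_usage("`abstol` must be > 0.")
  if (init_range <= 0) stop_usage("`init_range` must be > 0.")
  structure(list(epochs = as.integer(epochs), lambda = lambda,
                 abstol = abstol, init_range = init_range,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Min/range scaler mapping each training feature onto [0, 1]. A constant
# column gets range 1 so it scales to 0 rather than dividing by zero.
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mins <- apply(x, 2, min)
  rng <- apply(x, 2, max) - mins
  rng[rng == 0] <- 1
  list(min = mins, range = rng)
}

scale_features <- function(x, scaler) {
  x <- as.matrix(x)
  # test-time values outside the training range extrapolate; no clipping
  sweep(sweep(x, 2, scaler$min, "-"), 2, scaler$range, "/")
}

# Unpack the flat optimizer parameter vector into the two weight layers.
# W1 is (p+1) x H (row 1 = hidden biases), w2 has length H+1 (w2[1] = output
# bias, paired with a hidden activation fixed at 1).
unpack_weights <- function(par, nfeat, nhid) {
  list(W1 = matrix(par[seq_len((nfeat + 1) * nhid)],
                   nrow = nfeat + 1, ncol = nhid),
       w2 = par[(nfeat + 1) * nhid + seq_len(nhid + 1)])
}

nn_forward_scaled <- function(W1, w2, x1) {
  s <- plogis(x1 %*% W1)
  drop(w2[1] + s %*% w2[-1])
}

nn_objective_fn <- function(par, x1, y, lambda, nfeat, nhid) {
  w <- unpack_weights(par, nfeat, nhid)
  r <- nn_forward_scaled(w$W1, w$w2, x1) - y
  sum(r * r) + lambda * sum(par * par)
}

nn_gradient_fn <- function(par, x1, y, lambda, nfeat, nhid) {
  w <- unpack_weights(par, nfeat, nhid)
  z <- x1 %*% w$W1
  s <- plogis(z)
  r <- drop(w$w2[1] + s %*% w$w2[-1]) - y
  g2 <- 2 * c(sum(r), crossprod(s, r))
  delta <- (r %o% w$w2[-1]) * s * (1 - s)
  g1 <- 2 * crossprod(x1, delta)
  c(g1, g2) + 2 * lambda * par
}

#' Fit a single feed-forward network scoring function
#'
#' Trains a one-hidden-layer feed-forward network with logistic-sigmoid
#' hidden units, a linear output neuron and absorbed bias units on a feature
#' table. Inputs are min/range scaled to `[0, 1]` (scaling refit at every
#' call and stored in the model); the fit minimises the penalised
#' least-squares criterion
#' \deqn{E = \sum_n (y_n - \hat y_n)^2 + \lambda \sum_{i,j} w_{i,j}^2}
#' over all weights of both layers by full-batch BFGS with analytic
#' gradients, stopping after `epochs` iterations or once `E` falls below
#' `abstol`. Used directly, this is the SNN-Score single-network baseline;
#' it is also the base learner of [fit_bagging()] and [fit_boosting()].
#'
#' @param data A feature table (see [feature-table]).
#' @param features Character vector of descriptor columns to use; default all.
#' @param hidden Total number of hidden-layer neurons including the constant
#'   bias unit; `hidden = 20` means 19 sigmoid units.
#' @param config A [train_config()].
#' @return An object of class `snn_model` with elements `input_weights`
#'   ((p+1) x H matrix, first row the hidden biases), `output_weights`
#'   (length H+1, first entry the output bias), `features`, `scaler`,
#'   `config`, `objective` (final criterion value) and `converged`.
#' @export
#' @examples
#' sim <- generate_complexes(synthetic_spec(n = 80, seed = 7))
#' net <- train_network(sim$data, hidden = 8,
#'                      config = train_config(epochs = 100, seed = 1))
#' head(predict(net, sim$data))
train_network <- function(data, features = NULL, hidden = 20,
                          config = train_config()) {
  # bootstrap resamples legitimately repeat complexes, so IDs may duplicate
  validate_feature_table(data, allow_dup_ids = TRUE)
  stopifnot(inherits(config, "train_config"))
  if (hidden < 2) stop_usage("`hidden` counts the bias unit; need >= 2.")
  features <- features %||% feature_cols(data)
  if (length(features) == 0) stop_usage("No feature columns selected.")
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop_data(paste0("Feature column(s) absent from table: ",
                     paste(head(missing, 5), collapse = ", ")))
  }
  if (nrow(data) < 2) stop_usage("Need at least 2 training rows.")

  x <- as.matrix(data[features])
  y <- data$affinity
  scaler <- fit_scaler(x)
  x1 <- cbind(1, scale_features(x, scaler))
  p <- length(features)
  H <- hidden - 1L
  npar <- (p + 1) * H + H + 1

  par0 <- withr::with_seed(config$seed,
                           runif(npar, -config$init_range, config$init_range))
  fit <- optim(par0,
               function(w) nn_fn_cpp(w, x1, y, config$lambda, p, H),
               function(w) nn_gr_cpp(w, x1, y, config$lambda, p, H),
               method = "BFGS",
               control = list(maxit = config$epochs, abstol = config$abstol,
                              reltol = 1e-12))
  if (!all(is.finite(fit$par)) || !is.finite(fit$value)) {
    stop_numeric("Network training produced non-finite weights.")
  }
  w <- unpack_weights(fit$par, p, H)
  structure(list(input_weights = w$W1, output_weights = w$w2,
                 hidden = as.integer(hidden), features = features,
                 scaler = scaler, config = config,
                 objective = fit$value,
                 converged = fit$convergence == 0),
            class = "snn_model")
}

extract_feature_matrix <- function(object, newdata) {
  if (is.matrix(newdata)) {
    missing <- setdiff(object$features, colnames(newdata))
  } else {
    missing <- setdiff(object$features, names(newdata))
  }
  if (length(missing) > 0) {
    stop_data(paste0("Missing feature(s) for prediction: ",
                     paste(head(missing, 5), collapse = ", ")))
  }
  as.matrix(newdata[, object$features, drop = FALSE])
}

#' Predict binding affinity with a single network
#'
#' @param object An `snn_model`.
#' @param newdata A feature table (or matrix) containing the model's feature
#'   columns. Inputs are scaled by the training scaler; values outside the
#'   training range extrapolate.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities (-log K units).
#' @export
predict.snn_model <- function(object, newdata, ...) {
  x <- extract_feature_matrix(object, newdata)
  x1 <- cbind(1, scale_features(x, object$scaler))
  nn_forward_scaled(object$input_weights, object$output_weights, x1)
}

#' Penalised fitting criterion of a network on a dataset
#'
#' Evaluates the sum of squared prediction errors plus the weight-decay
#' penalty `lambda * sum(w^2)` over all weights of both layers, with
#' `lambda` taken from the model's training configuration.
#'
#' @param net An `snn_model`.
#' @param data A feature table.
#' @return The criterion value `E`.
#' @export
network_objective <- function(net, data) {
  validate_feature_table(data)
  r <- data$affinity - predict(net, data)
  wsum <- sum(net$input_weights^2) + sum(net$output_weights^2)
  sum(r * r) + net$config$lambda * wsum
}

#' @export
print.snn_model <- function(x, ...) {
  cat("<snn_model> single-network scoring function\n")
  cat("  features:", length(x$features),
      " hidden units (incl. bias):", x$hidden, "\n")
  cat("  final criterion E:", format(x$objective, digits = 6),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

#' @export
tidy.snn_model <- function(x, ...) {
  p1 <- expand.grid(from = seq_len(nrow(x$input_weights)) - 1L,
                    to = seq_len(ncol(x$input_weights)))
  dplyr::bind_rows(
    tibble::tibble(layer = "input-hidden", from = p1$from, to = p1$to,
                   weight = as.vector(x$input_weights)),
    tibble::tibble(layer = "hidden-output",
                   from = seq_along(x$output_weights) - 1L, to = 0L,
                   weight = x$output_weights)
  )
}

#' @export
glance.snn_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 hidden = x$hidden,
                 lambda = x$config$lambda,
                 objective = x$objective,
                 converged = x$converged)
}

#' @export
augment.snn_model <- function(x, data, ...) {
  pred <- predict(x, data)
  dplyr::mutate(data, .pred = pred, .resid = .data$affinity - pred)
}
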