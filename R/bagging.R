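# Seed discipline shared by both ensembles: the root seed expands to a 2 x L
# matrix of member seeds (row 1 drives resampling, row 2 weight init), so
# members can be trained in any order with identical results.
member_seeds <- function(seed, L) {
  withr::with_seed(as.integer(seed),
                   matrix(sample.int(.Machine$integer.max, 2L * L), nrow = 2L))
}

draw_member_design <- function(boot_seed, n, feature_names, subset_size,
                               bootstrap = TRUE) {
  withr::with_seed(boot_seed, {
    rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    feats <- sample(feature_names, min(subset_size, length(feature_names)))
    list(rows = rows, features = feats)
  })
}

# Non-finite members are refit with a bumped seed; members that merely fail
# to converge are kept (ensemble diversity benefits from them).
train_member <- function(data, features, hidden, config, init_seed,
                         max_retries = 3) {
  for (try in 0:max_retries) {
    cfg <- config
    cfg$seed <- as.integer((init_seed + try) %% .Machine$integer.max)
    net <- tryCatch(
      train_network(data, features = features, hidden = hidden, config = cfg),
      affinet_numeric_error = function(e) NULL)
    if (!is.null(net)) return(net)
  }
  stop_numeric("A member network failed to train after retries.")
}

#' Fit a bagged ensemble of networks (BgN-Score)
#'
#' Builds an ensemble of `L` single-hidden-layer networks. Each member is
#' trained on a bootstrap sample of the rows (drawn with replacement, same
#' size as the training set) and sees only a random subset of
#' `subset_size` features drawn without replacement, the random-subspace
#' device that decorrelates members. The ensemble predicts the plain average
#' of its members' outputs; rows left out of a member's bootstrap are that
#' member's out-of-bag validation set.
#'
#' @param data A feature table.
#' @param L Number of member networks. The benchmark setting is 3000;
#'   desk-scale experiments use far fewer.
#' @param subset_size Number of features per member (the benchmark uses 10,
#'   or 3 when only the 6 X-block features are available).
#' @param hidden Hidden neurons per member including the bias unit.
#' @param config A [train_config()]; its `seed` drives all resampling and
#'   initialisation.
#' @return A `bgn_ensemble`: members, their bootstrap row multisets,
#'   `subset_size` and the root seed.
#' @export
#' @examples
#' sim <- generate_complexes(synthetic_spec(n = 60, seed = 3))
#' ens <- fit_bagging(sim$data, L = 3, subset_size = 5, hidden = 6,
#'                    config = train_config(epochs = 50, seed = 1))
#' head(predict(ens, sim$data))
fit_bagging <- function(data, L = 3000, subset_size = 10, hidden = 20,
                        config = train_config()) {
  validate_feature_table(data)
  if (L < 1) stop_usage("`L` must be >= 1.")
  feats <- feature_cols(data)
  if (subset_size < 1 || subset_size > length(feats)) {
    stop_usage(paste0("`subset_size` must be in 1..", length(feats), "."))
  }
  if (nrow(data) < 2) stop_usage("Need at least 2 training rows.")
  seeds <- member_seeds(config$seed, L)
  n <- nrow(data)
  members <- vector("list", L)
  boots <- vector("list", L)
  for (l in seq_len(L)) {
    des <- draw_member_design(seeds[1, l], n, feats, subset_size)
    members[[l]] <- train_member(data[des$rows, , drop = FALSE],
                                 des$features, hidden, config, seeds[2, l])
    boots[[l]] <- des$rows
  }
  structure(list(members = members, bootstrap_index_sets = boots,
                 subset_size = as.integer(subset_size),
                 hidden = as.integer(hidden),
                 config = config, seed = config$seed,
                 n_train = n, train_ids = data$complex_id),
            class = "bgn_ensemble")
}

member_prediction_matrix <- function(members, newdata) {
  vapply(members, function(m) predict(m, newdata),
         numeric(nrow(as.data.frame(newdata))))
}

#' Predict binding affinity with a bagged ensemble
#'
#' The prediction is the arithmetic mean of the member networks' outputs,
#' each member seeing only its own feature subset.
#'
#' @param object A `bgn_ensemble`.
#' @param newdata A feature table containing every feature used by any
#'   member.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities.
#' @export
predict.bgn_ensemble <- function(object, newdata, ...) {
  pm <- member_prediction_matrix(object$members, newdata)
  if (nrow(as.data.frame(newdata)) == 1) pm <- matrix(pm, nrow = 1)
  rowMeans(pm)
}

#' Out-of-bag predictions of a bagged ensemble
#'
#' For each training row, averages the predictions of the members whose
#' bootstrap sample excluded that row (per-complex averaging). Rows sampled
#' by every member have no out-of-bag prediction and get `NA`.
#'
#' @param ens A `bgn_ensemble`.
#' @param data The training feature table the ensemble was fit on (matched
#'   by `complex_id`).
#' @return A tibble with `complex_id`, `affinity`, `.oob_pred` and
#'   `n_oob_members` (how many members voted).
#' @export
oob_predictions <- function(ens, data) {
  validate_feature_table(data)
  if (!identical(data$complex_id, ens$train_ids)) {
    stop_data("`data` does not match the ensemble's training rows.")
  }
  n <- nrow(data)
  pm <- member_prediction_matrix(ens$members, data)
  if (n == 1) pm <- matrix(pm, nrow = 1)
  oob_mask <- vapply(ens$bootstrap_index_sets, function(rows) {
    !(seq_len(n) %in% rows)
  }, logical(n))
  if (n == 1) oob_mask <- matrix(oob_mask, nrow = 1)
  votes <- rowSums(oob_mask)
  pred <- rowSums(pm * oob_mask) / votes
  pred[votes == 0] <- NA_real_
  tibble::tibble(complex_id = data$complex_id, affinity = data$affinity,
                 .oob_pred = pred, n_oob_members = as.integer(votes))
}

#' Out-of-bag RMSE of a bagged ensemble
#'
#' Root-mean-square error of the out-of-bag predictions over the covered
#' rows.
#'
#' @inheritParams oob_predictions
#' @return A single number.
#' @export
oob_rmse <- function(ens, data) {
  oob <- oob_predictions(ens, data)
  oob <- oob[!is.na(oob$.oob_pred), ]
  if (nrow(oob) == 0) stop_data("No out-of-bag coverage; increase L.")
  rmse(oob$affinity, oob$.oob_pred)
}

#' @export
print.bgn_ensemble <- function(x, ...) {
  cat("<bgn_ensemble> bagged network scoring function (BgN-Score)\n")
  cat("  members:", length(x$members),
      " feature subset size:", x$subset_size,
      " hidden units:", x$hidden, "\n")
  invisible(x)
}

#' @export
tidy.bgn_ensemble <- function(x, ...) {
  n <- x$n_train
  tibble::tibble(
    member = seq_along(x$members),
    n_oob = vapply(x$bootstrap_index_sets,
                   function(rows) sum(!(seq_len(n) %in% rows)), integer(1)),
    objective = vapply(x$members, function(m) m$objective, numeric(1)),
    features = lapply(x$members, function(m) m$features)
  )
}

#' @export
glance.bgn_ensemble <- function(x, ...) {
  tibble::tibble(L = length(x$members), subset_size = x$subset_size,
                 hidden = x$hidden, lambda = x$config$lambda,
                 n_train = x$n_train, seed = x$seed)
}

#' @export
augment.bgn_ensemble <- function(x, data, ...) {
  pred <- predict(x, data)
  dplyr::mutate(data, .pred = pred, .resid = .data$affinity - pred)
}
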