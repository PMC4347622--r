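#' Model serialization
#'
#' Trained scoring functions are written as self-contained JSON documents
#' (full-precision weights, feature subsets by column name, per-member
#' scalers, training configuration and a `format_version` field). Ensembles
#' embed their member networks in one document.
#'
#' @name model-io
NULL

.model_format_version <- "1.0"

snn_to_list <- function(net) {
  list(input_weights = net$input_weights,
       output_weights = net$output_weights,
       hidden = net$hidden,
       features = net$features,
       scaler = list(min = unname(net$scaler$min),
                     range = unname(net$scaler$range)),
       config = unclass(net$config),
       objective = net$objective,
       converged = net$converged)
}

snn_from_list <- function(x) {
  # JSON stores matrices row-wise
  W1 <- matrix(unlist(x$input_weights), nrow = length(x$features) + 1,
               byrow = TRUE)
  cfg <- do.call(train_config, x$config)
  structure(list(input_weights = W1,
                 output_weights = unlist(x$output_weights),
                 hidden = as.integer(x$hidden),
                 features = unlist(x$features),
                 scaler = list(min = setNames(unlist(x$scaler$min),
                                              unlist(x$features)),
                               range = setNames(unlist(x$scaler$range),
                                                unlist(x$features))),
                 config = cfg,
                 objective = x$objective,
                 converged = isTRUE(x$converged)),
            class = "snn_model")
}

#' Write a trained scoring function to JSON
#'
#' @param model An `snn_model`, `bgn_ensemble` or `bsn_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- if (inherits(model, "snn_model")) {
    c(list(format_version = .model_format_version, type = "snn"),
      snn_to_list(model))
  } else if (inherits(model, "bgn_ensemble")) {
    list(format_version = .model_format_version, type = "bgn",
         subset_size = model$subset_size, hidden = model$hidden,
         config = unclass(model$config), seed = model$seed,
         n_train = model$n_train, train_ids = model$train_ids,
         bootstrap_index_sets = model$bootstrap_index_sets,
         members = lapply(model$members, snn_to_list))
  } else if (inherits(model, "bsn_ensemble")) {
    list(format_version = .model_format_version, type = "bsn",
         nu = model$nu, residual_trace = model$residual_trace,
         subset_size = model$subset_size, hidden = model$hidden,
         config = unclass(model$config), seed = model$seed,
         n_train = model$n_train, train_ids = model$train_ids,
         members = lapply(model$members, snn_to_list))
  } else {
    stop_usage("`model` must be an snn_model, bgn_ensemble or bsn_ensemble.")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a trained scoring function from JSON
#'
#' @param path Path to a model document written by [write_model()].
#' @return The reconstructed model object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$type) || is.null(doc$format_version)) {
    stop_data(paste0("Not a model document: ", path))
  }
  cfg <- function() do.call(train_config, doc$config)
  switch(doc$type,
         snn = snn_from_list(doc),
         bgn = structure(
           list(members = lapply(doc$members, snn_from_list),
                bootstrap_index_sets = lapply(doc$bootstrap_index_sets,
                                              function(v) as.integer(unlist(v))),
                subset_size = as.integer(doc$subset_size),
                hidden = as.integer(doc$hidden), config = cfg(),
                seed = as.integer(doc$seed),
                n_train = as.integer(doc$n_train),
                train_ids = unlist(doc$train_ids)),
           class = "bgn_ensemble"),
         bsn = structure(
           list(members = lapply(doc$members, snn_from_list),
                nu = as.numeric(doc$nu),
                residual_trace = as.numeric(unlist(doc$residual_trace)),
                subset_size = as.integer(doc$subset_size),
                hidden = as.integer(doc$hidden), config = cfg(),
                seed = as.integer(doc$seed),
                n_train = as.integer(doc$n_train),
                train_ids = unlist(doc$train_ids)),
           class = "bsn_ensemble"),
         stop_data(paste0("Unknown model type: ", doc$type)))
}

#' Label a model in the Model::Features convention
#'
#' @param model A fitted model (or a character model name).
#' @param combo Feature-combination label, e.g. `"XARG"`.
#' @return A string such as `"BgN-Score::XARG"`.
#' @export
model_label <- function(model, combo) {
  name <- if (is.character(model)) {
    switch(model, snn = "SNN-Score", bgn = "BgN-Score", bsn = "BsN-Score",
           model)
  } else if (inherits(model, "bgn_ensemble")) {
    "BgN-Score"
  } else if (inherits(model, "bsn_ensemble")) {
    "BsN-Score"
  } else {
    "SNN-Score"
  }
  paste0(name, "::", paste0(parse_combo(combo), collapse = ""))
}
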