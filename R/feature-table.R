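#' Feature tables
#'
#' A feature table is an ordinary tibble holding one row per protein-ligand
#' complex: a `complex_id` column, an optional `family` column (protein-family
#' label), an `affinity` column with the measured binding affinity in
#' -log Kd / -log Ki units, and one numeric column per descriptor. Descriptor
#' columns carry their feature block in a name prefix: `"X."` (empirical
#' X-Score terms), `"A."` (AffiScore terms), `"R."` (element-pair contact
#' counts), `"G."` (GOLD descriptors). Columns without a recognised prefix are
#' tagged `OTHER`. All model-fitting and splitting functions in the package
#' take such a tibble as their first argument.
#'
#' @name feature-table
NULL

.reserved_cols <- c("complex_id", "family", "affinity")
.block_levels <- c("X", "A", "R", "G")

#' Feature columns and block tags of a feature table
#'
#' @param data A feature table (see [feature-table]).
#' @return `feature_cols()` returns the descriptor column names in table
#'   order. `block_tags()` returns a named character vector mapping each
#'   descriptor column to its block (`"X"`, `"A"`, `"R"`, `"G"` or `"OTHER"`).
#' @export
feature_cols <- function(data) {
  setdiff(names(data), .reserved_cols)
}

#' @rdname feature_cols
#' @export
block_tags <- function(data) {
  cols <- feature_cols(data)
  prefix <- sub("\\..*$", "", cols)
  tags <- ifelse(prefix %in% .block_levels & grepl(".", cols, fixed = TRUE),
                 prefix, "OTHER")
  setNames(tags, cols)
}

validate_feature_table <- function(data, call = rlang::caller_env(),
                                   allow_dup_ids = FALSE) {
  if (!is.data.frame(data)) {
    stop_usage("`data` must be a data frame feature table.", call = call)
  }
  if (!"complex_id" %in% names(data)) {
    stop_data("Feature table lacks a `complex_id` column.", call = call)
  }
  if (!"affinity" %in% names(data)) {
    stop_data("Feature table lacks an `affinity` column.", call = call)
  }
  if (!allow_dup_ids && anyDuplicated(data$complex_id)) {
    dup <- unique(data$complex_id[duplicated(data$complex_id)])
    stop_data(c("Duplicate complex IDs in feature table.",
                "x" = paste("First duplicates:",
                            paste(head(dup, 5), collapse = ", "))),
              call = call)
  }
  if (!all(is.finite(data$affinity))) {
    stop_data("All affinities must be finite.", call = call)
  }
  fc <- feature_cols(data)
  bad <- fc[!vapply(data[fc], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop_data(paste0("Non-numeric feature column(s): ",
                     paste(head(bad, 5), collapse = ", ")), call = call)
  }
  invisible(data)
}

#' Read a feature table from CSV
#'
#' Reads a comma-separated table with a header row into a feature table
#' tibble. Column roles default to the canonical names (`complex_id` or `id`,
#' `family`, `affinity`) and can be overridden through `schema`; block tags
#' are taken from the `"X."`/`"A."`/`"R."`/`"G."` name-prefix convention
#' unless `schema$blocks` supplies an explicit column-to-block map (those
#' columns are renamed to carry the prefix).
#'
#' @param path Path to a CSV file.
#' @param schema Optional list with any of `id`, `family`, `affinity` (column
#'   names in the file) and `blocks` (named character vector, column name ->
#'   block tag).
#' @return A feature table tibble; row order is preserved.
#' @export
read_feature_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop_usage(paste0("File not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  id_col <- schema$id %||% intersect(c("complex_id", "id"), names(raw))[1]
  if (is.na(id_col) || is.null(id_col) || !id_col %in% names(raw)) {
    stop_data("No complex-ID column found (expected `complex_id` or `id`).")
  }
  aff_col <- schema$affinity %||% "affinity"
  if (!aff_col %in% names(raw)) {
    stop_data(paste0("No affinity column `", aff_col, "` in ", path))
  }
  fam_col <- schema$family %||% (if ("family" %in% names(raw)) "family" else NULL)

  out <- tibble::tibble(complex_id = raw[[id_col]])
  if (!is.null(fam_col)) out$family <- raw[[fam_col]]
  out$affinity <- parse_numeric_col(raw[[aff_col]], aff_col)
  feat_names <- setdiff(names(raw), c(id_col, aff_col, fam_col))
  for (nm in feat_names) {
    out[[nm]] <- parse_numeric_col(raw[[nm]], nm)
  }
  if (!is.null(schema$blocks)) {
    out <- apply_block_schema(out, schema$blocks)
  }
  validate_feature_table(out)
  out
}

parse_numeric_col <- function(x, col) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) & !is.na(x) | is.na(x))
  if (length(bad) > 0) {
    stop_data(paste0("Non-numeric value in column `", col, "`, row ",
                     bad[1], ": \"", x[bad[1]], "\""))
  }
  val
}

apply_block_schema <- function(data, blocks) {
  bad_tags <- setdiff(unname(blocks), .block_levels)
  if (length(bad_tags) > 0) {
    stop_usage(paste0("Unknown block tag(s) in schema: ",
                      paste(bad_tags, collapse = ", ")))
  }
  for (col in names(blocks)) {
    if (!col %in% names(data)) {
      stop_usage(paste0("Schema names absent column `", col, "`."))
    }
    new <- paste0(blocks[[col]], ".", col)
    names(data)[names(data) == col] <- new
  }
  data
}

#' Write a feature table to CSV
#'
#' Numeric values are rendered with shortest round-trip precision, so
#' `read_feature_table(write_feature_table(x, p))` reproduces `x` bit for
#' bit.
#'
#' @param data A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  validate_feature_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Enumerate feature-block combinations
#'
#' All non-empty subsets of the available feature blocks, in a deterministic
#' order: by subset size, then by position in the canonical block order
#' X, A, R, G. Four blocks give the 15 combinations used throughout
#' PDBbind-style benchmarking.
#'
#' @param blocks Character vector of available block tags (subset of
#'   `c("X", "A", "R", "G")`).
#' @return A tibble with columns `combo` (label such as `"XAR"`) and
#'   `blocks` (list column of character vectors).
#' @export
#' @examples
#' enumerate_feature_combinations()           # 15 rows
#' enumerate_feature_combinations(c("X", "A"))
enumerate_feature_combinations <- function(blocks = .block_levels) {
  blocks <- unique(blocks)
  if (length(blocks) == 0) {
    stop_usage("`blocks` must contain at least one block tag.")
  }
  if (!all(blocks %in% .block_levels)) {
    stop_usage(paste0("Unknown block tag(s): ",
                      paste(setdiff(blocks, .block_levels), collapse = ", ")))
  }
  blocks <- .block_levels[.block_levels %in% blocks]
  subsets <- purrr::map(seq_along(blocks), function(k) {
    m <- utils::combn(blocks, k)
    purrr::map(seq_len(ncol(m)), function(j) m[, j])
  })
  subsets <- purrr::flatten(subsets)
  labels <- purrr::map_chr(subsets, paste0, collapse = "")
  ord <- order(lengths(subsets),
               purrr::map_chr(subsets, function(s) {
                 paste(sprintf("%02d", match(s, .block_levels)), collapse = "")
               }))
  tibble::tibble(combo = labels[ord], blocks = subsets[ord])
}

parse_combo <- function(combo) {
  if (is.character(combo) && length(combo) == 1 && !combo %in% .block_levels) {
    combo <- strsplit(combo, "")[[1]]
  }
  combo <- unique(combo)
  if (length(combo) == 0 || !all(combo %in% .block_levels)) {
    stop_usage(paste0("Invalid feature combination; blocks must come from ",
                      paste(.block_levels, collapse = ", "), "."))
  }
  .block_levels[.block_levels %in% combo]
}

#' Restrict a feature table to a block combination
#'
#' @param data A feature table.
#' @param combo A combination label such as `"XR"`, or a character vector of
#'   block tags.
#' @return The table with only the descriptor columns tagged by the requested
#'   blocks; IDs, family labels and affinities are untouched.
#' @export
select_features <- function(data, combo) {
  validate_feature_table(data)
  combo <- parse_combo(combo)
  tags <- block_tags(data)
  missing <- combo[!combo %in% tags]
  if (length(missing) > 0) {
    stop_data(paste0("No columns tagged for block(s): ",
                     paste(missing, collapse = ", ")))
  }
  keep <- names(tags)[tags %in% combo]
  data[, c(intersect(.reserved_cols, names(data)), keep)]
}

#' Refined-set / core-set split
#'
#' Splits a feature table into a training partition and a test partition
#' given the IDs of the benchmark core set, mirroring the construction of a
#' primary training set by removing all core complexes from a refined set.
#'
#' @param data A feature table.
#' @param core_ids Character vector of complex IDs forming the test (core)
#'   set. Must all be present in `data`.
#' @return A list with feature tables `train` and `test`.
#' @export
split_refined_core <- function(data, core_ids) {
  validate_feature_table(data)
  core_ids <- unique(as.character(core_ids))
  unknown <- setdiff(core_ids, data$complex_id)
  if (length(unknown) > 0) {
    stop_data(paste0("Core ID(s) not present in table: ",
                     paste(head(unknown, 5), collapse = ", ")))
  }
  in_core <- data$complex_id %in% core_ids
  list(train = data[!in_core, , drop = FALSE],
       test = data[in_core, , drop = FALSE])
}

#' Leave-one-protein-family-out split
#'
#' Holds out every complex of one protein family as a homogeneous test set;
#' all remaining complexes form the training set.
#'
#' @param data A feature table with a `family` column.
#' @param family The family label to hold out.
#' @return A list with feature tables `train` and `test`.
#' @export
family_holdout_split <- function(data, family) {
  validate_feature_table(data)
  if (!"family" %in% names(data)) {
    stop_data("Feature table has no `family` column.")
  }
  if (!family %in% data$family) {
    stop_data(paste0("Family not present in table: ", family))
  }
  test_rows <- data$family == family
  if (all(test_rows)) {
    stop_data("Holding out the only family would leave an empty training set.")
  }
  list(train = data[!test_rows, , drop = FALSE],
       test = data[test_rows, , drop = FALSE])
}

#' Reproducible k-fold partition of row indices
#'
#' Indices `1..n` are shuffled with the given seed and dealt round-robin into
#' `k` folds, so fold sizes differ by at most one.
#'
#' @param n Number of rows.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed controlling the shuffle.
#' @return A list of `k` sorted integer vectors partitioning `1:n`.
#' @export
kfold_indices <- function(n, k, seed) {
  if (k < 2 || k > n) {
    stop_usage("`k` must satisfy 2 <= k <= n.")
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  folds <- split(perm, rep_len(seq_len(k), n))
  unname(lapply(folds, sort))
}

#' Read a core-set ID list
#'
#' One complex ID per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the ID-list file.
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop_usage(paste0("File not found: ", path))
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids) & !startsWith(ids, "#")]
}
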