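test_that("CSV feature tables read back with roles and block tags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,family,affinity,X.f1,R.f1",
               "1a2b,kinase,6.5,0.1,3",
               "2c3d,kinase,4.2,-0.5,0",
               "3e4f,protease,8.0,1.25,7"), path)
  ds <- read_feature_table(path)
  expect_equal(nrow(ds), 3)
  expect_equal(ds$complex_id, c("1a2b", "2c3d", "3e4f"))
  expect_equal(unname(block_tags(ds)), c("X", "R"))
  expect_equal(ds$affinity, c(6.5, 4.2, 8.0))
  expect_equal(ds[["X.f1"]], c(0.1, -0.5, 1.25))
})

test_that("reader rejects malformed tables with classed errors", {
  bad_aff <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,affinity,X.f1", "a,NA,1", "b,2,2", "c,3,3"), bad_aff)
  expect_error(read_feature_table(bad_aff), class = "affinet_data_error")

  bad_feat <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,affinity,X.f1", "a,1,1", "b,2,oops"), bad_feat)
  err <- tryCatch(read_feature_table(bad_feat), error = function(e) e)
  expect_s3_class(err, "affinet_data_error")
  expect_match(conditionMessage(err), "X.f1")
  expect_match(conditionMessage(err), "row 2")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,affinity,X.f1", "a,1,1", "a,2,2"), dup)
  expect_error(read_feature_table(dup), class = "affinet_data_error")

  no_aff <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,X.f1", "a,1"), no_aff)
  expect_error(read_feature_table(no_aff), class = "affinet_data_error")
})

test_that("write/read round-trip preserves values to full precision", {
  ds <- withr::with_seed(99, {
    feats <- as.data.frame(matrix(rnorm(50 * 20) * 10^sample(-8:8, 1000,
                                                             TRUE),
                                  nrow = 50))
    names(feats) <- paste0(rep(c("X.", "A.", "R.", "G."), each = 5), 1:5)
    dplyr::bind_cols(tibble::tibble(complex_id = sprintf("c%02d", 1:50),
                                    family = sample(letters[1:5], 50, TRUE),
                                    affinity = rnorm(50)),
                     tibble::as_tibble(feats))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- read_feature_table(path)
  expect_identical(back$affinity, ds$affinity)
  for (col in feature_cols(ds)) expect_identical(back[[col]], ds[[col]])
  expect_identical(back$family, ds$family)
})

test_that("tables without features or family still round-trip", {
  ds <- tibble::tibble(complex_id = c("a", "b"), affinity = c(1.5, 2.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  expect_identical(readLines(path)[1], "complex_id,affinity")
  back <- read_feature_table(path)
  expect_equal(back$affinity, ds$affinity)
  expect_length(feature_cols(back), 0)
})

test_that("all non-empty block subsets are enumerated in stable order", {
  combos <- enumerate_feature_combinations()
  expect_equal(nrow(combos), 15)
  expect_equal(combos$combo[1:4], c("X", "A", "R", "G"))
  expect_equal(combos$combo[5:10], c("XA", "XR", "XG", "AR", "AG", "RG"))
  expect_equal(combos$combo[15], "XARG")

  expect_equal(enumerate_feature_combinations("X")$combo, "X")
  expect_equal(enumerate_feature_combinations(c("X", "A"))$combo,
               c("X", "A", "XA"))
  for (k in 1:4) {
    blocks <- c("X", "A", "R", "G")[1:k]
    expect_equal(nrow(enumerate_feature_combinations(blocks)), 2^k - 1)
  }
  expect_error(enumerate_feature_combinations(character(0)),
               class = "affinet_usage_error")
})

test_that("select_features restricts to tagged columns and is idempotent", {
  ds <- toy_table(n = 10, blocks = c(X = 6, R = 36))
  sel <- select_features(ds, "X")
  expect_length(feature_cols(sel), 6)
  expect_equal(sel$affinity, ds$affinity)
  expect_identical(select_features(sel, "X"), sel)
  expect_identical(feature_cols(select_features(ds, c("X", "R"))),
                   feature_cols(ds))
  expect_error(select_features(ds, "G"), class = "affinet_data_error")
})

test_that("refined/core split partitions the table exactly", {
  ds <- toy_table(n = 40)
  core <- ds$complex_id[c(3, 7, 21, 40)]
  sp <- split_refined_core(ds, core)
  expect_setequal(sp$test$complex_id, core)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ds))
  expect_length(intersect(sp$train$complex_id, sp$test$complex_id), 0)

  empty <- split_refined_core(ds, character(0))
  expect_equal(nrow(empty$train), 40)
  expect_equal(nrow(empty$test), 0)
  all_in <- split_refined_core(ds, ds$complex_id)
  expect_equal(nrow(all_in$train), 0)
  expect_error(split_refined_core(ds, "nope"),
               class = "affinet_data_error")
})

test_that("family holdout keeps families disjoint and covers all IDs", {
  ds <- dplyr::bind_rows(
    dplyr::mutate(toy_table(10, seed = 1), family = "F1",
                  complex_id = sprintf("A%02d", 1:10)),
    dplyr::mutate(toy_table(5, seed = 2), family = "F2",
                  complex_id = sprintf("B%02d", 1:5)))
  sp <- family_holdout_split(ds, "F2")
  expect_equal(nrow(sp$test), 5)
  expect_equal(nrow(sp$train), 10)
  expect_false("F2" %in% sp$train$family)

  for (f in unique(ds$family)) {
    sp <- family_holdout_split(ds, f)
    expect_setequal(c(sp$train$complex_id, sp$test$complex_id),
                    ds$complex_id)
  }
  expect_error(family_holdout_split(ds, "F9"), class = "affinet_data_error")

  single <- dplyr::mutate(ds, family = "F1")
  expect_error(family_holdout_split(single, "F1"),
               class = "affinet_data_error")
})

test_that("k-fold partitions are balanced, seeded and distinct by seed", {
  folds <- kfold_indices(10, 10, seed = 4)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 1))

  folds <- kfold_indices(7, 3, seed = 4)
  expect_setequal(unlist(folds), 1:7)
  expect_setequal(lengths(folds), c(3, 2, 2))

  expect_identical(kfold_indices(20, 4, seed = 9),
                   kfold_indices(20, 4, seed = 9))
  base <- kfold_indices(20, 4, seed = 1)
  differing <- sum(vapply(2:101, function(s) {
    !identical(kfold_indices(20, 4, seed = s), base)
  }, logical(1)))
  expect_gte(differing, 99)

  expect_error(kfold_indices(5, 6, seed = 1), class = "affinet_usage_error")
})
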