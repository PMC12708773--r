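# small noise-free library shared by the modelling tests
mod_lib <- generate_library(synthetic_config(n_molecules = 120, seed = 21))
mod_split <- stratified_split(mod_lib, seed = 4)
mod_grid <- enumerate_grid(list(
  n_estimators = c(5L, 50L), max_depth = c(2L, 4L), learning_rate = 0.1,
  colsample_bytree = 0.9, reg_lambda = 0.01, min_child_weight = 7))

test_that("the full grid is the Cartesian product of the axes", {
  expect_equal(nrow(enumerate_grid()), 7 * 9 * 3 * 3 * 5 * 4)  # 11,340
  one <- enumerate_grid(list(n_estimators = 5L, max_depth = 2L,
                             learning_rate = 0.1, colsample_bytree = 0.5,
                             reg_lambda = 0, min_child_weight = 7))
  expect_equal(nrow(one), 1L)
  expect_error(enumerate_grid(list(n_estimators = integer(0), max_depth = 2L,
                                   learning_rate = 0.1,
                                   colsample_bytree = 0.5, reg_lambda = 0,
                                   min_child_weight = 7)), "empty")
  expect_error(enumerate_grid(list(n_estimators = 300L, max_depth = 2L,
                                   learning_rate = 0.1,
                                   colsample_bytree = 0.5, reg_lambda = 0,
                                   min_child_weight = 7)), "domain")
})

test_that("selection honours the accuracy-spread constraint deterministically", {
  fit1 <- train_with_constraint(mod_lib, mod_split, "ECFP4-1024",
                                grid = mod_grid, seed = 2)
  fit2 <- train_with_constraint(mod_lib, mod_split, "ECFP4-1024",
                                grid = mod_grid, seed = 2)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(predict(fit1$model, mod_lib), predict(fit2$model, mod_lib))
  sel <- fit1$log[fit1$log$selected, ]
  expect_lte(sel$spread, 0.05)
  expect_true(all(!fit1$log$selected | fit1$log$constraint_ok))
  # discarded points are flagged, not dropped
  expect_equal(nrow(fit1$log), nrow(mod_grid))
  expect_error(train_with_constraint(mod_lib, mod_split, "ECFP4-1024",
                                     grid = mod_grid, max_spread = -1),
               "constraint")
})

test_that("a model round-trips through serialization with identical predictions", {
  fit <- train_with_constraint(mod_lib, mod_split, "MACCS-167",
                               grid = mod_grid[1:2, ], seed = 2)
  p0 <- predict(fit$model, mod_lib)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit$model, path)
  p1 <- predict(readRDS(path), mod_lib)
  expect_identical(p0, p1)
  expect_true(all(p0 >= 0 & p0 <= 1))
})

test_that("evaluation reports confusion-consistent metrics", {
  fit <- train_with_constraint(mod_lib, mod_split, "ECFP6-1024",
                               grid = mod_grid, seed = 2)
  test_lib <- mod_lib[mod_lib$id %in% mod_split$test_ids, ]
  rep <- evaluate(fit$model, test_lib)
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, nrow(test_lib))
  expect_equal(rep$accuracy,
               (rep$tp + rep$tn) / (rep$tp + rep$tn + rep$fp + rep$fn))
  expect_error(evaluate(fit$model, test_lib[0, ]), "empty|missing")
  # single-class set: AUC absent, the rest computed
  one_class <- mod_lib[mod_lib$label == "active", ][1:5, ]
  rep1 <- evaluate(fit$model, one_class)
  expect_true(is.na(rep1$auc))
  expect_false(is.na(rep1$accuracy))
  # stability report never feeds back into selection; just shape + values
  stab <- stability_report(fit$model, mod_lib, mod_split)
  expect_true(all(c("acc_train", "acc_validation", "acc_test") %in% names(stab)))
})

test_that("stratified cross-validation balances folds and recovers the rule", {
  lib100 <- fake_library(100, 0.5)
  expect_error(cross_validate(lib100[c(1:6, 51:56), ], "ECFP4-1024",
                              mod_grid[1, ], k = 10),
               "at least k")
  params <- list(n_estimators = 25L, max_depth = 3L, learning_rate = 0.1,
                 colsample_bytree = 0.9, reg_lambda = 0.01,
                 min_child_weight = 7)
  cv <- cross_validate(mod_lib, "ECFP4-1024", params, k = 10, seed = 13)
  # fold sizes are balanced per class
  for (cl in c("active", "inactive")) {
    per_fold <- table(cv$fold_assignment[mod_lib$label == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  # noise-free implanted rule is recoverable
  expect_gte(cv$mean[["accuracy"]], 0.9)
})
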