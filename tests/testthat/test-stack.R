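test_that("stack configuration validates its roster", {
  cfg <- stack_config()
  expect_length(cfg$base_learners, 6)
  expect_setequal(cfg$base_learners,
                  c("extra_trees", "mlp", "gbt_shallow", "gbt_depth5",
                    "gbt_deep", "voting"))
  expect_equal(cfg$cv_folds, 5)
  expect_setequal(cfg$features, c("C3", "C4", "SumC3C4", "C3C4"))

  expect_error(stack_config("rotation_forest"), "Valid names")
  expect_error(stack_config(character(0)), "at least|At least")
  expect_error(stack_config(cv_folds = 1), "cv_folds")
  expect_error(stack_config(features = c("C3", "age")), "never")

  # Table 2 overrides round-trip through config
  cfg2 <- stack_config("knn", params = list(knn = list(k = 9)))
  expect_equal(cfg2$specs$knn$k, 9)
  expect_error(stack_config("knn", params = list(bogus = list(a = 1))),
               "unknown learner")

  # a single-base stack is a valid degenerate stack
  m <- train_stack(toy_dataset(10), stack_config("knn", cv_folds = 2),
                   seed = 1)
  expect_s3_class(m, "cvd_stack")
})

test_that("shipped hyperparameter defaults carry the tuned values", {
  s <- base_learner_specs()
  expect_equal(s$svm[c("kernel", "cost")], list(kernel = "radial", cost = 800))
  expect_equal(s$knn$k, 4)
  expect_equal(s$random_forest, list(num_trees = 211, max_depth = 13))
  expect_equal(s$extra_trees, list(num_trees = 63, max_depth = 12))
  expect_equal(s$mlp, list(hidden = 20, decay = 1e-4, max_iter = 300))
  expect_equal(s$gbt_shallow,
               list(nrounds = 100, max_depth = 3, eta = 0.2,
                    subsample = 0.9, colsample_bytree = 0.85))
  expect_equal(s$gbt_depth5, list(nrounds = 100, max_depth = 5, eta = 0.1))
  expect_equal(s$gbt_deep, list(nrounds = 1000, max_depth = 10, eta = 0.1))
  expect_setequal(s$voting$members, c("svm", "knn", "random_forest"))
})

test_that("the full stack separates a separable toy table perfectly", {
  d <- toy_dataset(20, gap = 6)
  fit <- train_stack(d, seed = 3)
  expect_equal(mean(predict(fit, d) == d$Maturation), 1)
})

test_that("training is reproducible and probabilities are coherent", {
  d <- toy_dataset(15, gap = 2)
  holdout <- toy_dataset(10, seed = 456, gap = 2)
  f1 <- train_stack(d, seed = 11)
  f2 <- train_stack(d, seed = 11)
  p1 <- predict(f1, holdout, type = "prob")
  expect_identical(p1, predict(f2, holdout, type = "prob"))

  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_true(all(p1 >= 0))
  # argmax of probabilities equals the class prediction
  expect_identical(as.integer(colnames(p1)[max.col(p1, "first")]),
                   predict(f1, holdout))
  # labels stay in the trained set
  expect_true(all(predict(f1, holdout) %in% 1:3))
})

test_that("age and gender never influence predictions", {
  d <- toy_dataset(15)
  fit <- train_stack(d, seed = 2)
  holdout <- toy_dataset(8, seed = 9)
  base <- predict(fit, holdout, type = "prob")
  mangled <- holdout
  mangled$age <- mangled$age * 100
  mangled$gender <- "F"
  expect_identical(predict(fit, mangled, type = "prob"), base)
  stripped <- holdout[setdiff(names(holdout), c("age", "gender"))]
  expect_identical(predict(fit, stripped, type = "prob"), base)

  # training with age/gender removed gives the identical model output
  fit2 <- train_stack(d[setdiff(names(d), c("age", "gender"))], seed = 2)
  expect_identical(predict(fit2, holdout, type = "prob"), base)
})

test_that("training fails cleanly on degenerate inputs", {
  d <- toy_dataset(10)
  expect_error(train_stack(d[d$Maturation != 2, ], seed = 1),
               "classes 1, 2 and 3")
  d_inf <- d
  d_inf$C3[1] <- Inf
  expect_error(train_stack(d_inf, seed = 1), "finite")
  expect_error(predict(build_stack(), d), "train_stack")
  expect_error(train_stack(d[, c("C3", "C4", "Maturation")], seed = 1),
               "missing column")
})

test_that("monotone extrapolation holds far beyond the training range", {
  d <- toy_dataset(20, gap = 6)
  fit <- train_stack(d, seed = 4)
  far <- tibble::tibble(C3 = 100, C4 = 100, SumC3C4 = 200, C3C4 = 10000)
  expect_equal(predict(fit, far), 3L)
})

test_that("permutation importance zeroes out uninformative features and is reproducible", {
  d <- toy_dataset(20, gap = 4)
  # an all-constant feature: shuffling it cannot change predictions
  d$C4 <- 5.5
  d <- add_ratio_features(d)
  fit <- train_stack(d, stack_config(c("extra_trees", "knn"), cv_folds = 3),
                     seed = 6)
  imp <- feature_importance(fit, d, seed = 10)
  expect_s3_class(imp, "cvd_importance")
  expect_identical(imp$importance[imp$feature == "C4"], 0)
  expect_gt(max(imp$importance), 0.1)
  imp2 <- feature_importance(fit, d, seed = 10)
  expect_identical(imp, imp2)
})

test_that("tidy and glance summarise a fitted stack", {
  d <- toy_dataset(10)
  fit <- train_stack(d, stack_config("knn", cv_folds = 2), seed = 1)
  td <- tidy(fit)
  expect_true(all(c("class", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_train, 30)
  expect_equal(gl$n_base_learners, 1)
  expect_error(tidy(build_stack()), "untrained")
})

test_that("training row order does not move test accuracy materially", {
  co <- simulate_cohort(dplyr::mutate(class_profiles(), n = 60), seed = 15)
  sp <- split_dataset(co, seed = 15)
  cfg <- stack_config(c("extra_trees", "gbt_shallow"), cv_folds = 3)
  f_a <- train_stack(sp$train, cfg, seed = 20)
  shuffled <- sp$train[withr::with_seed(1, sample(nrow(sp$train))), ]
  f_b <- train_stack(shuffled, cfg, seed = 20)
  acc_a <- mean(predict(f_a, sp$test) == sp$test$Maturation)
  acc_b <- mean(predict(f_b, sp$test) == sp$test$Maturation)
  expect_lt(abs(acc_a - acc_b), 0.05)
})
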