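test_that("folds are disjoint, exhaustive and near-equal", {
  folds <- kfold_split(470, 10, seed = 1)
  expect_length(folds, 10L)
  expect_true(all(lengths(folds) == 47L))
  expect_identical(sort(unlist(folds)), 1:470)

  singles <- kfold_split(10, 10, seed = 1)
  expect_true(all(lengths(singles) == 1L))

  uneven <- kfold_split(23, 10, seed = 2)
  expect_true(all(lengths(uneven) %in% c(2L, 3L)))
  expect_identical(sort(unlist(uneven)), 1:23)

  expect_identical(kfold_split(50, 10, seed = 3), kfold_split(50, 10, seed = 3))
  expect_false(identical(kfold_split(50, 10, seed = 3),
                         kfold_split(50, 10, seed = 4)))
  expect_error(kfold_split(5, 10), "at least K")
})

test_that("stratified folds balance the classes", {
  y <- rep(c(0L, 1L), c(30, 70))
  folds <- kfold_split(100, 10, seed = 1, stratify_by = y)
  expect_identical(sort(unlist(folds)), 1:100)
  per_fold_ones <- vapply(folds, function(f) sum(y[f]), integer(1))
  expect_true(all(per_fold_ones == 7L))
})

test_that("fold accuracies of a constant predictor equal the held-out label rates", {
  # 60% of labels are 1; a stub that always predicts 1 must score, on each
  # fold, exactly the fraction of 1s that fold holds.
  n <- 100
  y <- rep(c(1L, 0L), c(60, 40))
  X <- cbind(matrix(1, n, 3), seq_len(n))  # last column = sample id
  folds <- kfold_split(n, 10, seed = 5)
  cv <- cross_validate(X, y, stub_constant_config(1L), K = 10, seed = 5)
  expected <- vapply(folds, function(f) 100 * mean(y[f] == 1L), numeric(1))
  expect_equal(unname(cv$fold_accuracies), unname(expected))
  expect_equal(cv$mean_accuracy, mean(expected))
  expect_equal(cv$sigma, sd(expected))
})

test_that("a perfect oracle scores 100 with zero spread", {
  n <- 50
  y <- rep(c(0L, 1L), 25)
  X <- cbind(matrix(0, n, 3), seq_len(n))
  cv <- cross_validate(X, y, oracle_config(y), K = 10, seed = 1)
  expect_identical(cv$mean_accuracy, 100)
  expect_identical(cv$sigma, 0)
})

test_that("fold hygiene: no index is in both train and test of any fold", {
  folds <- kfold_split(97, 10, seed = 9)
  for (k in seq_along(folds)) {
    train <- setdiff(1:97, folds[[k]])
    expect_length(intersect(train, folds[[k]]), 0L)
    expect_identical(sort(c(train, folds[[k]])), 1:97)
  }
})

test_that("mean and sigma are recomputable from the fold accuracies", {
  d <- generate_dataset(60, seed = 2)
  fm <- features_matrix(d)
  cfg <- model_config("FFNN_1L", neurons_l1 = 10, activation = "ReLU",
                      epochs = 30, seed = 1)
  cv <- cross_validate(fm$X, fm$y, cfg, K = 10, seed = 3)
  expect_identical(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_identical(cv$sigma, sd(cv$fold_accuracies))
  expect_length(cv$fold_accuracies, 10L)
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 100))
})

test_that("the default grid enumerates the documented configuration space", {
  grid <- default_grid()
  fams <- vapply(grid, function(g) g$family, character(1))
  expect_identical(sum(fams == "SVM"), 2L)
  expect_identical(sum(fams == "FFNN_1L"), 30L)  # 3 activations x 10 sizes
  expect_identical(sum(fams == "FFNN_2L"), 81L)  # 9 act pairs x 9 size pairs
  one <- grid[fams == "FFNN_1L"]
  acts <- vapply(one, function(g) g$activation, character(1))
  expect_identical(unique(acts), c("Tanh", "Sigmoid", "ReLU"))
  neurons <- vapply(one[acts == "ReLU"], function(g) g$neurons_l1, integer(1))
  expect_identical(neurons, seq(10L, 100L, by = 10L))
  two <- grid[fams == "FFNN_2L"]
  pairs <- t(vapply(two, function(g) c(g$neurons_l1, g$neurons_l2),
                    integer(2)))
  expect_true(all(pairs %in% c(50L, 70L, 90L)))
})

test_that("grid search ranks by accuracy with sigma and size tie-breaks", {
  n <- 60
  y <- rep(c(0L, 1L), 30)
  X <- cbind(matrix(0, n, 3), seq_len(n))
  res <- grid_search(X, y, list(stub_constant_config(1L), oracle_config(y)),
                     K = 10, seed = 2)
  expect_s3_class(res, "grid_search_result")
  expect_identical(res[[1]]$mean_accuracy, 100)
  expect_lt(res[[2]]$mean_accuracy, 100)
})

test_that("single-config grids reduce to plain cross-validation", {
  d <- generate_dataset(40, seed = 3)
  fm <- features_matrix(d)
  cfg <- model_config("FFNN_1L", neurons_l1 = 10, activation = "ReLU",
                      epochs = 20, seed = 1)
  res <- grid_search(fm$X, fm$y, list(cfg), K = 5, seed = 4)
  cv <- cross_validate(fm$X, fm$y, cfg, K = 5, seed = 4)
  expect_equal(res[[1]]$fold_accuracies, cv$fold_accuracies)
})

test_that("the report table mirrors the evaluation column set", {
  d <- generate_dataset(40, seed = 5)
  fm <- features_matrix(d)
  grid <- default_grid(families = c("SVM", "FFNN_1L"),
                       neurons_1l = 10L, epochs = 10L)
  res <- grid_search(fm$X, fm$y, grid, K = 5, seed = 1)
  df <- as.data.frame(res)
  expect_identical(names(df),
                   c("family", "kernel", "neurons_l1", "neurons_l2",
                     "activation", "mean_accuracy", "sigma"))
  expect_identical(nrow(df), 5L)  # 2 SVM + 3 activations x 1 size
  dir <- withr::local_tempdir()
  write_report(res, file.path(dir, "report.csv"), file.path(dir, "report.txt"))
  expect_identical(nrow(read.csv(file.path(dir, "report.csv"))), 5L)
  expect_true(any(grepl("\\+/-", readLines(file.path(dir, "report.txt")))))
})

test_that("grid search is deterministic end to end for a fixed seed", {
  d <- generate_dataset(40, seed = 6)
  fm <- features_matrix(d)
  grid <- default_grid(families = "FFNN_1L", neurons_1l = c(10L, 20L),
                       epochs = 15L, seed = 1)
  a <- as.data.frame(grid_search(fm$X, fm$y, grid, K = 5, seed = 2))
  b <- as.data.frame(grid_search(fm$X, fm$y, grid, K = 5, seed = 2))
  expect_identical(a, b)
})

test_that("the selected model is the argmax config retrained on all data", {
  d <- generate_dataset(50, seed = 7)
  fm <- features_matrix(d)
  grid <- default_grid(families = "FFNN_1L", neurons_1l = c(10L, 20L),
                       activations = "ReLU", epochs = 30L, seed = 1)
  res <- grid_search(fm$X, fm$y, grid, K = 5, seed = 3)
  model <- select_and_retrain(fm$X, fm$y, res, seed = 3)
  best <- res[[1]]
  expect_identical(model$config, best$config)
  expect_identical(attr(model, "cv"), best)
  train_acc <- 100 * mean(predict(model, fm$X)$label == fm$y)
  expect_gte(train_acc, best$mean_accuracy)
})
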