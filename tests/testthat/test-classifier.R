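# Small separable fixture: adequate rows have large areas in all slices,
# inadequate rows near zero.
separable_data <- function(n = 60, seed = 1) {
  d <- generate_dataset(n, seed = seed)
  features_matrix(d)
}

test_that("configurations validate their family-specific fields", {
  cfg <- model_config("FFNN_1L", neurons_l1 = 20, activation = "ReLU")
  expect_identical(n_parameters(cfg), 441L)  # 20*20+20 hidden, 20+1 head
  arch <- build_model(cfg)
  expect_identical(arch$head, "sigmoid")

  cfg2 <- model_config("FFNN_2L", neurons_l1 = 90, neurons_l2 = 90,
                       activation = "ReLU")
  arch2 <- build_model(cfg2)
  expect_identical(arch2$hidden, c(90L, 90L))
  expect_identical(arch2$head, "softmax")

  expect_error(model_config("FFNN_1L", neurons_l1 = 20, neurons_l2 = 10,
                            activation = "ReLU"), "neurons_l2")
  expect_error(model_config("FFNN_1L", neurons_l1 = 20,
                            activation = "Swish"))
  expect_error(model_config("SVM", svm_kernel = "polynomial"))
  expect_error(model_config("SVM", neurons_l1 = 5), "no network fields")
})

test_that("two-layer parameter counts follow the architecture arithmetic", {
  cfg <- model_config("FFNN_2L", neurons_l1 = 50, neurons_l2 = 70,
                      activation = "Tanh")
  expect_identical(n_parameters(cfg),
                   as.integer(20 * 50 + 50 + 50 * 70 + 70 + 70 * 2 + 2))
})

test_that("zero-weight networks score exactly 0.5 and ties go to inadequate", {
  cfg1 <- model_config("FFNN_1L", neurons_l1 = 4, activation = "ReLU")
  m1 <- ffnn_model(cfg1,
                   weights = list(matrix(0, 20, 4), matrix(0, 4, 1)),
                   biases = list(rep(0, 4), 0))
  p1 <- predict(m1, rep(10, 20))
  expect_identical(p1$score, 0.5)
  expect_identical(p1$label, 0L)

  cfg2 <- model_config("FFNN_2L", neurons_l1 = 4, neurons_l2 = 3,
                       activation = "Tanh")
  m2 <- ffnn_model(cfg2,
                   weights = list(matrix(0, 20, 4), matrix(0, 4, 3),
                                  matrix(0, 3, 2)),
                   biases = list(rep(0, 4), rep(0, 3), rep(0, 2)))
  p2 <- predict(m2, rep(10, 20))
  expect_identical(p2$score, 0.5)
  expect_identical(p2$label, 0L)
})

test_that("training separates the synthetic classes within 100 epochs", {
  fm <- separable_data(80, seed = 2)
  for (family in list(model_config("FFNN_1L", neurons_l1 = 20,
                                   activation = "ReLU", seed = 1),
                      model_config("FFNN_2L", neurons_l1 = 50,
                                   neurons_l2 = 50, activation = "ReLU",
                                   seed = 1))) {
    m <- fit_model(family, fm$X, fm$y)
    expect_identical(predict(m, fm$X)$label, fm$y)
    expect_length(m$history, 100L)
  }
})

test_that("held-out samples from the same distribution are classified correctly", {
  fm <- separable_data(80, seed = 3)
  m <- fit_model(model_config("FFNN_1L", neurons_l1 = 20,
                              activation = "ReLU", seed = 1), fm$X, fm$y)
  held <- separable_data(40, seed = 99)
  expect_identical(predict(m, held$X)$label, held$y)
})

test_that("training is deterministic given the seed", {
  fm <- separable_data(40, seed = 4)
  probe <- separable_data(20, seed = 5)
  cfg <- model_config("FFNN_1L", neurons_l1 = 10, activation = "Tanh",
                      seed = 7)
  a <- fit_model(cfg, fm$X, fm$y)
  b <- fit_model(cfg, fm$X, fm$y)
  expect_identical(predict(a, probe$X), predict(b, probe$X))
  c <- fit_model(cfg, fm$X, fm$y, seed = 8)
  expect_false(identical(a$weights, c$weights))
})

test_that("degenerate single-class training still predicts that class", {
  fm <- separable_data(20, seed = 6)
  keep <- fm$y == 1L
  m <- fit_model(model_config("FFNN_1L", neurons_l1 = 5,
                              activation = "Sigmoid", seed = 1),
                 fm$X[keep, , drop = FALSE], fm$y[keep])
  expect_true(all(predict(m, fm$X[keep, , drop = FALSE])$label == 1L))
})

test_that("invalid training inputs are rejected", {
  fm <- separable_data(20, seed = 7)
  cfg <- model_config("FFNN_1L", neurons_l1 = 5, activation = "ReLU")
  Xbad <- fm$X; Xbad[1, 1] <- -3
  expect_error(fit_model(cfg, Xbad, fm$y), "non-negative")
  Xnan <- fm$X; Xnan[2, 2] <- NaN
  expect_error(fit_model(cfg, Xnan, fm$y), "finite")
  m <- fit_model(cfg, fm$X, fm$y)
  expect_error(predict(m, rep(1, 19)), "input dimension")
})

test_that("scores always lie in [0, 1] and labels are binary", {
  fm <- separable_data(40, seed = 8)
  for (cfg in list(model_config("FFNN_1L", neurons_l1 = 10,
                                activation = "Sigmoid", seed = 2),
                   model_config("SVM", svm_kernel = "gaussian"))) {
    m <- fit_model(cfg, fm$X, fm$y)
    p <- predict(m, fm$X)
    expect_true(all(p$score >= 0 & p$score <= 1))
    expect_true(all(p$label %in% c(0L, 1L)))
  }
})

test_that("SVM baselines separate trivially separable data", {
  X <- rbind(rep(0, 20), rep(100, 20))
  y <- c(0L, 1L)
  m <- train_svm_baseline(X, y, "linear")
  expect_identical(predict(m, X)$label, y)

  fm <- separable_data(60, seed = 9)
  ml <- train_svm_baseline(fm$X, fm$y, "linear")
  expect_identical(predict(ml, fm$X)$label, fm$y)
  mg <- train_svm_baseline(fm$X, fm$y, "gaussian")
  expect_true(all(predict(mg, fm$X)$label %in% c(0L, 1L)))

  expect_error(train_svm_baseline(fm$X, fm$y, "sigmoid"))
  expect_error(train_svm_baseline(fm$X, rep(1L, nrow(fm$X)), "linear"),
               "each class")
})

test_that("models round-trip through the single-file format", {
  fm <- separable_data(30, seed = 10)
  m <- fit_model(model_config("FFNN_1L", neurons_l1 = 10,
                              activation = "ReLU", seed = 3), fm$X, fm$y)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, fm$X), predict(m, fm$X))
  expect_identical(back$config$neurons_l1, 10L)
})
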