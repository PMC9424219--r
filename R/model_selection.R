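#' K-fold index split
#'
#' Shuffles `1..n` by the seed and deals the indices into `K` disjoint
#' folds whose sizes differ by at most one. Not stratified by default;
#' set `stratify_by` to a label vector to balance classes across folds.
#'
#' @param n Number of samples.
#' @param K Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify_by Optional label vector of length `n`.
#' @return List of `K` integer index vectors.
#' @export
kfold_split <- function(n, K = 10L, seed = 0L, stratify_by = NULL) {
  stopifnot(is_count(n), is_count(K, 1L), is_count(seed))
  if (n < K) stop("need at least K samples for K folds", call. = FALSE)
  with_seed(seed, {
    if (is.null(stratify_by)) {
      idx <- sample.int(n)
      unname(split(idx, rep_len(seq_len(K), n)))
    } else {
      stopifnot(length(stratify_by) == n)
      folds <- vector("list", K)
      for (cls in unique(stratify_by)) {
        ci <- sample(which(stratify_by == cls))
        assign_to <- rep_len(seq_len(K), length(ci))
        for (k in seq_len(K)) {
          folds[[k]] <- c(folds[[k]], ci[assign_to == k])
        }
      }
      folds
    }
  })
}

#' Cross-validate one configuration
#'
#' K-fold cross-validation: the model is trained K times, each time
#' holding one fold out as the test set, and scored by the percentage of
#' correct classifications on the held-out fold. Reports the per-fold
#' accuracies, their mean, and the 1-sigma repeatability (sample standard
#' deviation, n-1 denominator).
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param config A configuration dispatched through [fit_model()].
#' @param K Number of folds (default 10).
#' @param seed Seed for the fold split and per-fold training.
#' @param stratified Stratify folds by label (off by default).
#' @return A `cv_result`: `config`, `fold_accuracies` (%), `mean_accuracy`
#'   and `sigma`.
#' @export
cross_validate <- function(X, y, config, K = 10L, seed = 0L,
                           stratified = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 1L)
  folds <- kfold_split(nrow(X), K, seed,
                       stratify_by = if (stratified) y else NULL)
  acc <- vapply(seq_along(folds), function(k) {
    test <- folds[[k]]
    train <- setdiff(seq_len(nrow(X)), test)
    model <- fit_model(config, X[train, , drop = FALSE], y[train],
                       seed = seed + k)
    pred <- predict(model, X[test, , drop = FALSE])
    100 * mean(pred$label == y[test])
  }, numeric(1))
  cv_result(config, acc)
}

cv_result <- function(config, fold_accuracies) {
  stopifnot(all(fold_accuracies >= 0), all(fold_accuracies <= 100))
  structure(list(config = config, fold_accuracies = fold_accuracies,
                 mean_accuracy = mean(fold_accuracies),
                 sigma = sd(fold_accuracies)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  id <- tryCatch(config_id(x$config), error = function(e) class(x$config)[1])
  cat(sprintf("<cv_result %s: %.1f +/- %.1f %% over %d folds>\n",
              id, x$mean_accuracy, x$sigma, length(x$fold_accuracies)))
  invisible(x)
}

#' The default hyper-parameter grid
#'
#' Enumerated in a fixed, documented order: SVM (linear, gaussian); then
#' one-hidden-layer networks, activation-major (Tanh, Sigmoid, ReLU) with
#' 10..100 neurons in steps of 10; then two-hidden-layer networks over all
#' activation pairs (same activation order, layer-1-major) and all neuron
#' pairs from \{50, 70, 90\} per layer.
#'
#' @param families Subset of `c("SVM", "FFNN_1L", "FFNN_2L")` to include.
#' @param neurons_1l Neuron counts for the one-layer family.
#' @param neurons_2l Neuron counts per layer for the two-layer family.
#' @param activations Activation functions, in grid order.
#' @param epochs,batch_size,seed Passed to every configuration.
#' @return List of [model_config()] objects.
#' @export
default_grid <- function(families = c("SVM", "FFNN_1L", "FFNN_2L"),
                         neurons_1l = seq(10L, 100L, by = 10L),
                         neurons_2l = c(50L, 70L, 90L),
                         activations = c("Tanh", "Sigmoid", "ReLU"),
                         epochs = 100L, batch_size = 5L, seed = 0L) {
  grid <- list()
  if ("SVM" %in% families) {
    for (k in c("linear", "gaussian")) {
      grid <- c(grid, list(model_config("SVM", svm_kernel = k, seed = seed)))
    }
  }
  if ("FFNN_1L" %in% families) {
    for (a in activations) {
      for (n1 in neurons_1l) {
        grid <- c(grid, list(model_config("FFNN_1L", neurons_l1 = n1,
                                          activation = a, epochs = epochs,
                                          batch_size = batch_size,
                                          seed = seed)))
      }
    }
  }
  if ("FFNN_2L" %in% families) {
    for (a1 in activations) {
      for (a2 in activations) {
        for (n1 in neurons_2l) {
          for (n2 in neurons_2l) {
            grid <- c(grid, list(model_config("FFNN_2L", neurons_l1 = n1,
                                              neurons_l2 = n2,
                                              activation = c(a1, a2),
                                              epochs = epochs,
                                              batch_size = batch_size,
                                              seed = seed)))
          }
        }
      }
    }
  }
  grid
}

#' Cross-validate every configuration in a grid
#'
#' Runs [cross_validate()] for each configuration and ranks the results
#' by mean accuracy (descending), breaking ties by smaller sigma, then by
#' fewer parameters.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param grid List of configurations (see [default_grid()]).
#' @param K Number of folds.
#' @param seed Seed shared by every configuration's fold split, so all
#'   models see identical folds.
#' @param verbose Print one progress line per configuration.
#' @return A `grid_search_result`: ranked list of `cv_result`s.
#' @export
grid_search <- function(X, y, grid, K = 10L, seed = 0L, verbose = FALSE) {
  stopifnot(length(grid) >= 1L)
  results <- lapply(grid, function(cfg) {
    r <- cross_validate(X, y, cfg, K = K, seed = seed)
    if (verbose) print(r)
    r
  })
  means <- vapply(results, function(r) r$mean_accuracy, numeric(1))
  sigmas <- vapply(results, function(r) r$sigma, numeric(1))
  pars <- vapply(results, function(r) {
    p <- tryCatch(n_parameters(r$config, ncol(X)), error = function(e) NA)
    if (is.na(p)) .Machine$integer.max else p
  }, numeric(1))
  ord <- order(-means, sigmas, pars)
  structure(results[ord], class = "grid_search_result")
}

#' Tabulate grid-search results
#'
#' One row per configuration with the column set of the evaluation
#' report: family, kernel, neurons per layer, activation, and accuracy
#' mean and 1-sigma repeatability (%).
#'
#' @param x A `grid_search_result`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return A data.frame, rows in rank order.
#' @export
as.data.frame.grid_search_result <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  do.call(rbind, lapply(x, function(r) {
    cfg <- r$config
    data.frame(family = cfg$family,
               kernel = if (is.null(cfg$svm_kernel)) NA_character_
                        else cfg$svm_kernel,
               neurons_l1 = cfg$neurons_l1,
               neurons_l2 = cfg$neurons_l2,
               activation = if (is.null(cfg$activation)) NA_character_
                            else paste(cfg$activation, collapse = "+"),
               mean_accuracy = r$mean_accuracy,
               sigma = r$sigma)
  }))
}

#' Write the grid-search report
#'
#' CSV plus a formatted text table (accuracy shown as `mean +/- sigma`).
#'
#' @param results A `grid_search_result`.
#' @param csv_path,txt_path Output paths (`NULL` to skip either).
#' @return The report data.frame, invisibly.
#' @export
write_report <- function(results, csv_path = NULL, txt_path = NULL) {
  df <- as.data.frame(results)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    shown <- df
    shown$accuracy <- sprintf("%.1f +/- %.1f", df$mean_accuracy, df$sigma)
    shown$mean_accuracy <- NULL
    shown$sigma <- NULL
    writeLines(utils::capture.output(print(shown, row.names = FALSE)),
               txt_path)
  }
  invisible(df)
}

#' Select the best configuration and retrain on all data
#'
#' Takes the top-ranked configuration of a grid search and refits it on
#' the entire dataset, so the deployed model uses every labelled sample.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param results A `grid_search_result` (or list of `cv_result`s, best
#'   first).
#' @param seed Seed for the final fit.
#' @return The fitted model with the winning `cv_result` attached as
#'   attribute `"cv"`.
#' @export
select_and_retrain <- function(X, y, results, seed = 0L) {
  stopifnot(length(results) >= 1L)
  best <- results[[1]]
  model <- fit_model(best$config, X, y, seed = seed)
  attr(model, "cv") <- best
  model
}
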