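#' Classifier configuration
#'
#' Describes one model of the evaluation zoo: a feed-forward network with
#' one hidden layer (single sigmoid output unit), a network with two
#' hidden layers (two-unit softmax head), or an SVM baseline with linear
#' or gaussian kernel. Networks train with binary cross-entropy and the
#' Adam optimizer; defaults of 100 epochs and batch size 5 match the
#' evaluation protocol.
#'
#' @param family `"FFNN_1L"`, `"FFNN_2L"` or `"SVM"`.
#' @param neurons_l1 Hidden-layer-1 size (FFNN families).
#' @param neurons_l2 Hidden-layer-2 size (FFNN_2L only).
#' @param activation Hidden activation(s): `"ReLU"`, `"Tanh"` or
#'   `"Sigmoid"`. For FFNN_2L either one name (both layers) or two.
#' @param svm_kernel `"linear"` or `"gaussian"` (SVM only).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 5).
#' @param seed Seed for weight initialization and shuffling.
#' @param standardize SVM only: standardize features before fitting.
#'   Off by default, mirroring the no-scaling protocol for the networks.
#' @return An object of class `model_config`.
#' @examples
#' model_config("FFNN_1L", neurons_l1 = 20, activation = "ReLU")
#' @export
model_config <- function(family = c("FFNN_1L", "FFNN_2L", "SVM"),
                         neurons_l1 = NULL, neurons_l2 = NULL,
                         activation = NULL, svm_kernel = NULL,
                         epochs = 100L, batch_size = 5L, seed = 0L,
                         standardize = FALSE) {
  family <- match.arg(family)
  stopifnot(is_count(epochs, 1L), is_count(batch_size, 1L), is_count(seed))
  if (family == "SVM") {
    if (!is.null(neurons_l1) || !is.null(neurons_l2) || !is.null(activation)) {
      stop("SVM configs take no network fields", call. = FALSE)
    }
    svm_kernel <- match.arg(svm_kernel, c("linear", "gaussian"))
  } else {
    if (!is.null(svm_kernel)) {
      stop("svm_kernel only applies to the SVM family", call. = FALSE)
    }
    stopifnot(is_count(neurons_l1, 1L))
    activation <- vapply(activation, function(a) {
      match.arg(a, c("ReLU", "Tanh", "Sigmoid"))
    }, character(1), USE.NAMES = FALSE)
    if (family == "FFNN_1L") {
      if (!is.null(neurons_l2)) {
        stop("neurons_l2 set for a one-hidden-layer network", call. = FALSE)
      }
      if (length(activation) != 1L) {
        stop("FFNN_1L takes exactly one activation", call. = FALSE)
      }
    } else {
      stopifnot(is_count(neurons_l2, 1L))
      if (length(activation) == 1L) activation <- rep(activation, 2L)
      if (length(activation) != 2L) {
        stop("FFNN_2L takes one or two activations", call. = FALSE)
      }
    }
  }
  structure(list(family = family,
                 neurons_l1 = if (is.null(neurons_l1)) NA_integer_
                              else as.integer(neurons_l1),
                 neurons_l2 = if (is.null(neurons_l2)) NA_integer_
                              else as.integer(neurons_l2),
                 activation = activation, svm_kernel = svm_kernel,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), standardize = standardize),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config ", config_id(x), ">\n", sep = "")
  invisible(x)
}

config_id <- function(config) {
  if (config$family == "SVM") {
    paste0("SVM/", config$svm_kernel)
  } else if (config$family == "FFNN_1L") {
    paste0("FFNN_1L/", config$neurons_l1, "/", config$activation)
  } else {
    paste0("FFNN_2L/", config$neurons_l1, "-", config$neurons_l2, "/",
           paste(config$activation, collapse = "-"))
  }
}

#' Number of learnable parameters of a network configuration
#'
#' Weights plus biases over all layers, input dimension `n_features`
#' (default 20). `NA` for SVM configs.
#'
#' @param config A [model_config()].
#' @param n_features Input dimension.
#' @return Integer parameter count, or `NA`.
#' @export
n_parameters <- function(config, n_features = 20L) {
  if (config$family == "SVM") return(NA_integer_)
  n1 <- config$neurons_l1
  if (config$family == "FFNN_1L") {
    as.integer(n_features * n1 + n1 + n1 * 1L + 1L)
  } else {
    n2 <- config$neurons_l2
    as.integer(n_features * n1 + n1 + n1 * n2 + n2 + n2 * 2L + 2L)
  }
}

#' Build an untrained model shell
#'
#' Validates the configuration and returns the architecture description
#' (layer sizes, activations, head, loss, optimizer) without fitting.
#'
#' @param config A [model_config()].
#' @param n_features Input dimension (default 20).
#' @return A list describing the architecture.
#' @export
build_model <- function(config, n_features = 20L) {
  stopifnot(inherits(config, "model_config"))
  if (config$family == "SVM") {
    return(list(config = config, kernel = config$svm_kernel))
  }
  hidden <- if (config$family == "FFNN_1L") {
    config$neurons_l1
  } else {
    c(config$neurons_l1, config$neurons_l2)
  }
  list(config = config, input_dim = n_features, hidden = hidden,
       activations = config$activation,
       head = if (config$family == "FFNN_1L") "sigmoid" else "softmax",
       loss = "binary cross-entropy", optimizer = "Adam",
       n_parameters = n_parameters(config, n_features))
}

.ACT_CODES <- c(ReLU = 1L, Tanh = 2L, Sigmoid = 3L)

#' Fit a perfusion classifier
#'
#' Generic training entry point dispatched on the configuration class, so
#' the cross-validation harness works with any classifier exposing a
#' `fit_model()` method and a `predict()` method on the fitted object.
#'
#' @param config A configuration object (usually a [model_config()]).
#' @param X Numeric feature matrix, one row per sample.
#' @param y Binary label vector (1 adequate / 0 inadequate).
#' @param seed Optional seed overriding the config's own.
#' @param ... Passed to methods.
#' @return A fitted model; for [model_config()] a `perfusion_model`.
#' @export
fit_model <- function(config, X, y, seed = NULL, ...) {
  UseMethod("fit_model")
}

validate_training_data <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("features must be finite and non-negative (histogram areas)",
         call. = FALSE)
  }
  if (!all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
}

#' @rdname fit_model
#' @export
fit_model.model_config <- function(config, X, y, seed = NULL, ...) {
  validate_training_data(X, y)
  if (is.null(seed)) seed <- config$seed
  if (config$family == "SVM") {
    return(fit_svm(config, X, y, seed))
  }
  arch <- build_model(config, n_features = ncol(X))
  fit <- ffnn_train_cpp(X, as.numeric(y),
                        hidden = as.integer(arch$hidden),
                        act_codes = .ACT_CODES[arch$activations],
                        head_units = if (arch$head == "sigmoid") 1L else 2L,
                        epochs = config$epochs,
                        batch_size = config$batch_size,
                        lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                        adam_eps = 1e-8, seed = as.integer(seed))
  ffnn_model(config, fit$weights, fit$biases, history = as.numeric(fit$loss))
}

#' Assemble a network model from explicit parameters
#'
#' Low-level constructor used by the trainer and by serialization;
#' also handy for inspecting degenerate parameter settings.
#'
#' @param config A network [model_config()].
#' @param weights List of weight matrices, input to output.
#' @param biases List of bias vectors, one per weight matrix.
#' @param history Per-epoch training loss (may be `NULL`).
#' @return A `perfusion_model`.
#' @export
ffnn_model <- function(config, weights, biases, history = NULL) {
  stopifnot(config$family %in% c("FFNN_1L", "FFNN_2L"),
            length(weights) == length(biases))
  structure(list(config = config, weights = weights, biases = biases,
                 history = history, kind = "ffnn"),
            class = "perfusion_model")
}

fit_svm <- function(config, X, y, seed) {
  if (length(unique(y)) < 2L) {
    stop("SVM training needs at least one sample of each class",
         call. = FALSE)
  }
  kernel <- if (config$svm_kernel == "linear") "linear" else "radial"
  gamma <- if (kernel == "radial") {
    # Median heuristic: bandwidth from the median pairwise distance.
    d2 <- stats::dist(if (nrow(X) > 200) X[seq_len(200), , drop = FALSE]
                      else X)^2
    med <- stats::median(d2[d2 > 0])
    if (!is.finite(med) || med == 0) 1 / ncol(X) else 1 / med
  } else {
    1 / ncol(X)
  }
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
                    kernel = kernel, gamma = gamma,
                    scale = isTRUE(config$standardize))
  structure(list(config = config, svm = fit, kind = "svm"),
            class = "perfusion_model")
}

#' Train an SVM baseline
#'
#' Convenience wrapper building an SVM [model_config()] and fitting it.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param kernel `"linear"` or `"gaussian"`.
#' @param seed Seed (kept for interface symmetry; libsvm fitting is
#'   deterministic here).
#' @param standardize Standardize features before fitting (off by
#'   default).
#' @return A fitted `perfusion_model`.
#' @export
train_svm_baseline <- function(X, y, kernel = c("linear", "gaussian"),
                               seed = 0L, standardize = FALSE) {
  kernel <- match.arg(kernel)
  cfg <- model_config("SVM", svm_kernel = kernel, seed = seed,
                      standardize = standardize)
  fit_model(cfg, X, y)
}

ffnn_forward <- function(model, X) {
  A <- X
  L <- length(model$weights)
  acts <- model$config$activation
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A %*% model$weights[[l]], 2, model$biases[[l]], `+`)
    A <- switch(acts[l],
                ReLU = pmax(Z, 0),
                Tanh = tanh(Z),
                Sigmoid = 1 / (1 + exp(-Z)))
  }
  Z <- sweep(A %*% model$weights[[L]], 2, model$biases[[L]], `+`)
  if (model$config$family == "FFNN_1L") {
    as.numeric(1 / (1 + exp(-Z)))
  } else {
    E <- exp(Z - apply(Z, 1, max))
    P <- E / rowSums(E)
    P[, 2]  # probability of class 1 (adequate)
  }
}

#' Predict perfusion from feature vectors
#'
#' Returns a score in `[0, 1]` (probability of adequate perfusion) and the
#' binary label. The decision threshold is 0.5 with ties mapped to
#' inadequate (0), so uncertain cases are flagged for review.
#'
#' @param object A fitted `perfusion_model`.
#' @param newdata Feature matrix (rows = samples) or a single feature
#'   vector.
#' @param ... Unused.
#' @return A data.frame with columns `score` and `label`.
#' @export
predict.perfusion_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  expected <- if (object$kind == "ffnn") {
    nrow(object$weights[[1]])
  } else {
    ncol(object$svm$SV)
  }
  if (ncol(newdata) != expected) {
    stop("feature vector length ", ncol(newdata), " does not match the ",
         "model's input dimension ", expected, call. = FALSE)
  }
  if (object$kind == "ffnn") {
    score <- ffnn_forward(object, newdata)
  } else {
    pred <- predict(object$svm, newdata, decision.values = TRUE)
    d <- as.numeric(attr(pred, "decision.values"))
    dname <- colnames(attr(pred, "decision.values"))[1]
    # libsvm's decision value is positive for the first-named class.
    if (!is.null(dname) && startsWith(dname, "0")) d <- -d
    score <- stats::plogis(d)
    # Keep the label consistent with libsvm's own decision.
    lab <- as.integer(as.character(pred))
    return(data.frame(score = score, label = lab))
  }
  data.frame(score = score, label = as.integer(score > 0.5))
}

#' @export
print.perfusion_model <- function(x, ...) {
  cat("<perfusion_model ", config_id(x$config), ">\n", sep = "")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Single-file serialized format with the configuration embedded.
#'
#' @param model A `perfusion_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "perfusion_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "perfusion_model")) {
    stop("file does not contain a perfusion model: ", path, call. = FALSE)
  }
  model
}
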