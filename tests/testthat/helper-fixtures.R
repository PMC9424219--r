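# Shared fixtures: small scene parameter sets, brute-force oracles, and
# stub classifiers for exercising the cross-validation harness
# independently of the real models.

quiet_params <- function(...) {
  scene_params(roi_width = 40, roi_height = 20, green_sigma = 0,
               noise_sd = 0, ...)
}

# Per-pixel brute-force oracle for the slice features: count green >= k in
# each of n equal vertical slices (unit bins).
naive_features <- function(patch, k = 25, n_slices = 20) {
  w <- dim(patch)[2]
  bounds <- floor((0:n_slices) * w / n_slices)
  vapply(seq_len(n_slices), function(i) {
    g <- patch[, (bounds[i] + 1):bounds[i + 1], 2]
    sum(g >= k)
  }, numeric(1))
}

# Two-pass brute-force PSR: peak, then mean/sd over all pixels outside the
# 11x11 exclusion square, computed with explicit loops over coordinates.
naive_psr <- function(resp, exclude = 11) {
  best <- -Inf; pr <- 0; pc <- 0
  for (r in seq_len(nrow(resp))) {
    for (c in seq_len(ncol(resp))) {
      if (resp[r, c] > best) { best <- resp[r, c]; pr <- r; pc <- c }
    }
  }
  half <- exclude %/% 2
  side <- c()
  for (r in seq_len(nrow(resp))) {
    for (c in seq_len(ncol(resp))) {
      if (abs(r - pr) > half || abs(c - pc) > half) {
        side <- c(side, resp[r, c])
      }
    }
  }
  s <- sd(side)
  if (length(side) < 2 || s == 0) return(Inf)
  (best - mean(side)) / s
}

# Stub classifiers for the CV harness. Registered against the package
# namespace so S3 dispatch inside cross_validate() finds them.
stub_constant_config <- function(label) {
  structure(list(label = label), class = "stub_constant")
}
registerS3method("fit_model", "stub_constant",
                 function(config, X, y, seed = NULL, ...) {
                   structure(list(label = config$label), class = "stub_model")
                 },
                 envir = asNamespace("icgperfusion"))

oracle_config <- function(truth) {
  structure(list(truth = truth), class = "stub_oracle")
}
registerS3method("fit_model", "stub_oracle",
                 function(config, X, y, seed = NULL, ...) {
                   structure(list(truth = config$truth, oracle = TRUE),
                             class = "stub_model")
                 },
                 envir = asNamespace("icgperfusion"))

registerS3method("predict", "stub_model",
                 function(object, newdata, ...) {
                   n <- nrow(newdata)
                   if (isTRUE(object$oracle)) {
                     # Recover the truth by matching rows to sample ids
                     # stored in the last feature column.
                     lab <- object$truth[newdata[, ncol(newdata)]]
                   } else {
                     lab <- rep(object$label, n)
                   }
                   data.frame(score = as.numeric(lab), label = as.integer(lab))
                 },
                 envir = asNamespace("icgperfusion"))
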