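#' Statistical decision container
#'
#' @param test Test name.
#' @param statistic Test statistic value.
#' @param p_value Two-sided p-value.
#' @param alpha Significance level (default 0.01).
#' @param df Degrees of freedom (scalar or length 2).
#' @return An object of class `stat_decision`; `decision` is `"REJECT"`
#'   iff `p_value < alpha`.
#' @export
stat_decision <- function(test, statistic, p_value, alpha = 0.01, df = NULL) {
  stopifnot(is_number(p_value), p_value >= 0, p_value <= 1,
            is_number(alpha), alpha > 0, alpha < 1)
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 alpha = alpha, df = df,
                 decision = if (p_value < alpha) "REJECT"
                            else "FAIL_TO_REJECT"),
            class = "stat_decision")
}

#' @export
print.stat_decision <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, alpha = %g -> %s\n",
              x$test, x$statistic, x$p_value, x$alpha, x$decision))
  invisible(x)
}

#' One-way ANOVA (Fisher test)
#'
#' Classical fixed-effects one-way analysis of variance across two or
#' more groups, with the F statistic referred to its exact F tail
#' probability. Used to test whether the mean cross-validation accuracies
#' of the activation-function groups come from one population.
#'
#' @param groups List of two or more numeric vectors, each of length two
#'   or more.
#' @param alpha Significance level (default 0.01).
#' @return A [stat_decision()].
#' @export
one_way_anova <- function(groups, alpha = 0.01) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) >= 2L))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    stop("degenerate input: zero within-group variance", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups),
                       vapply(groups, length, integer(1))))
  fit <- oneway.test(values ~ labels, var.equal = TRUE)
  stat_decision("one-way ANOVA (Fisher)",
                statistic = unname(fit$statistic),
                p_value = fit$p.value, alpha = alpha,
                df = unname(fit$parameter))
}

#' Paired t-test
#'
#' Two-sided paired Student t-test on the per-condition differences
#' `a - b`, with the exact t tail probability. Sidedness is two-sided:
#' the question is whether a group differs from another, in either
#' direction.
#'
#' @param a,b Numeric vectors of equal length (>= 2), paired by position.
#' @param alpha Significance level (default 0.01).
#' @return A [stat_decision()].
#' @export
paired_t_test <- function(a, b, alpha = 0.01) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b),
            length(a) >= 2L)
  d <- a - b
  if (sd(d) == 0) {
    stop("degenerate input: the paired differences have zero variance",
         call. = FALSE)
  }
  fit <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  stat_decision("paired t-test", statistic = unname(fit$statistic),
                p_value = fit$p.value, alpha = alpha,
                df = unname(fit$parameter))
}

#' Compare activation-function accuracy groups
#'
#' The validation stage of the model-selection protocol: a one-way ANOVA
#' (Fisher test) across the Tanh, Sigmoid and ReLU mean-accuracy columns,
#' followed by the three pairwise paired t-tests (Tanh-Sigmoid,
#' Tanh-ReLU, ReLU-Sigmoid), all at the same significance level.
#'
#' @param acc_table Data.frame or matrix with columns `tanh`, `sigmoid`
#'   and `relu` (case-insensitive): per-neuron-count mean CV accuracies.
#' @param alpha Significance level (default 0.01).
#' @return Named list of four [stat_decision()]s: `fisher_anova`,
#'   `t_tanh_sigmoid`, `t_tanh_relu`, `t_relu_sigmoid`.
#' @examples
#' compare_activation_groups(activation_accuracy_grid())
#' @export
compare_activation_groups <- function(acc_table, alpha = 0.01) {
  tbl <- as.data.frame(acc_table)
  names(tbl) <- tolower(names(tbl))
  need <- c("tanh", "sigmoid", "relu")
  if (!all(need %in% names(tbl))) {
    stop("need columns tanh, sigmoid and relu", call. = FALSE)
  }
  g <- lapply(tbl[need], as.numeric)
  list(fisher_anova = one_way_anova(g, alpha),
       t_tanh_sigmoid = paired_t_test(g$tanh, g$sigmoid, alpha),
       t_tanh_relu = paired_t_test(g$tanh, g$relu, alpha),
       t_relu_sigmoid = paired_t_test(g$relu, g$sigmoid, alpha))
}

#' Published activation-function accuracy grid
#'
#' Mean and 1-sigma cross-validation accuracy (%) of the one-hidden-layer
#' network for the three activation functions over hidden sizes 10..100,
#' as reported in the clinical evaluation of this method; shipped with
#' the package as the reference input of the statistical validation
#' example.
#'
#' @return Data.frame with columns `neurons`, `tanh`, `tanh_sd`,
#'   `sigmoid`, `sigmoid_sd`, `relu`, `relu_sd`.
#' @export
activation_accuracy_grid <- function() {
  read.csv(system.file("extdata", "activation_grid_accuracy.csv",
                       package = "icgperfusion"))
}

#' Write a statistical-validation report
#'
#' One row per test: name, null hypothesis, alpha, p-value and decision.
#'
#' @param decisions Named list of [stat_decision()]s, as returned by
#'   [compare_activation_groups()].
#' @param path Output CSV path.
#' @return The report data.frame, invisibly.
#' @export
write_stat_report <- function(decisions, path) {
  df <- do.call(rbind, lapply(names(decisions), function(nm) {
    d <- decisions[[nm]]
    data.frame(test = d$test, comparison = nm,
               H0 = "same distribution", alpha = d$alpha,
               statistic = d$statistic, p_value = d$p_value,
               decision = d$decision)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
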