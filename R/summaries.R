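#' Geometric mean
#'
#' Pharmacokinetic parameters are treated as log-normally distributed, so
#' cohort central tendency is the geometric mean, exp(mean(ln x)).
#'
#' @param x Positive numeric values, `n >= 1`.
#' @return The geometric mean, in the units of `x`.
#' @examples
#' geometric_mean(c(4, 16)) # 8
#' @export
geometric_mean <- function(x) {
  check_positive(x, n_min = 1L)
  exp(mean(log(x)))
}

#' Geometric-mean confidence interval
#'
#' Exponentiated t-interval on the natural-log scale:
#' exp(mean_ln +/- t(n-1, 1-alpha/2) * sd_ln / sqrt(n)).
#'
#' @inheritParams geometric_mean
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
geometric_ci <- function(x, level = 0.95) {
  check_positive(x, n_min = 2L)
  stopifnot(level > 0, level < 1)
  lx <- log(x)
  n <- length(x)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(lx) / sqrt(n)
  setNames(exp(mean(lx) + c(-1, 1) * half), c("lower", "upper"))
}

check_positive <- function(x, n_min) {
  if (length(x) < n_min) abort(paste0("Need at least ", n_min, " value(s)."))
  if (any(!is.finite(x) | x <= 0)) {
    abort("All values must be positive and finite (log-scale statistic).")
  }
  invisible(x)
}

#' Median, range and order-statistic interquartile range
#'
#' The median is the middle order statistic (mean of the two middles for even
#' n). Quartiles use the nearest-rank fourths convention: the order
#' statistics at ranks ceiling((n+1)/4) and ceiling(3(n+1)/4), i.e. ranks 4
#' and 12 for n = 15. This convention returns observed values, the usual
#' practice in clinical PK reporting.
#'
#' @param x Numeric values, `n >= 1` (positivity not required).
#' @return One-row tibble: `n`, `median`, `min`, `max`, `q1`, `q3`.
#' @export
descriptive <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) abort("Need at least one finite value.")
  s <- sort(x)
  n <- length(s)
  tibble::tibble(
    n = n, median = median(s), min = s[1L], max = s[n],
    q1 = s[min(n, ceiling((n + 1) / 4))], q3 = s[min(n, ceiling(3 * (n + 1) / 4))]
  )
}

#' Log-scale two-sample comparison of geometric means
#'
#' Equal-variance (Student's) two-sample t-test on ln-transformed values.
#' The back-transformed difference of log means is the ratio of geometric
#' means of group A to group B, with its exponentiated confidence interval
#' and the two-sided p-value.
#'
#' @param values_a,values_b Positive values of the two groups, each `n >= 2`.
#' @param level Confidence level, default 0.95.
#' @param var_equal Pool the variances (Student's test, default) or not
#'   (Welch).
#' @return Object of class `gm_comparison` with elements
#'   `ratio_of_geometric_means`, `ci` (`lower`, `upper`), `p_value`,
#'   `t_statistic`, `df`, `n_a`, `n_b`, `level`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' compare_groups_log_t(c(16.5, 15.1, 12.7), c(11.7, 12.3, 9.2))
#' @export
compare_groups_log_t <- function(values_a, values_b, level = 0.95,
                                 var_equal = TRUE) {
  check_positive(values_a, 2L)
  check_positive(values_b, 2L)
  tt <- t.test(log(values_a), log(values_b), var.equal = var_equal,
               conf.level = level)
  structure(
    list(
      ratio_of_geometric_means = exp(mean(log(values_a)) - mean(log(values_b))),
      ci = setNames(exp(tt$conf.int), c("lower", "upper")),
      p_value = unname(tt$p.value),
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      n_a = length(values_a), n_b = length(values_b),
      level = level, var_equal = var_equal
    ),
    class = "gm_comparison"
  )
}

#' @export
print.gm_comparison <- function(x, ...) {
  cat(sprintf(
    "<gm_comparison> ratio of geometric means %.3g (%g%% CI %.3g-%.3g), p = %.3g (n = %d vs %d, %s t-test on logs)\n",
    x$ratio_of_geometric_means, 100 * x$level, x$ci[["lower"]], x$ci[["upper"]],
    x$p_value, x$n_a, x$n_b, if (x$var_equal) "Student's" else "Welch's"))
  invisible(x)
}

nca_parameters <- c("cmax_pf", "cmax_pl", "t_half_pf", "t_half_pl",
                    "auc90_pf", "auc90_pl", "auc_total_pl", "auc_ratio")

#' Cohort summary table of noncompartmental parameters
#'
#' One row per pharmacokinetic parameter with the geometric mean, its
#' t-based confidence interval on the log scale, and the median / range /
#' order-statistic IQR, each computed over the evaluable (non-missing)
#' patients with `n` reported.
#'
#' @param results Per-patient results, e.g. from [run_nca()] or
#'   [reference_nca()].
#' @param parameters Character vector of result columns to summarise;
#'   defaults to the eight standard parameters that are present.
#' @param level Confidence level for the geometric-mean CI.
#' @return Tibble: `parameter`, `n`, `geometric_mean`, `ci_lower`,
#'   `ci_upper`, `median`, `min`, `max`, `q1`, `q3`.
#' @export
build_summary_table <- function(results, parameters = NULL, level = 0.95) {
  parameters <- parameters %||% intersect(nca_parameters, names(results))
  if (!length(parameters)) abort("No summarisable parameter columns found.")
  purrr::map_dfr(parameters, function(p) {
    x <- results[[p]]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      abort(paste0("Parameter `", p, "` has fewer than 2 evaluable values; ",
                   "a confidence interval is undefined."))
    }
    ci <- geometric_ci(x, level)
    d <- descriptive(x)
    tibble::tibble(
      parameter = p, n = d$n, geometric_mean = geometric_mean(x),
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      median = d$median, min = d$min, max = d$max, q1 = d$q1, q3 = d$q3
    )
  })
}

report_digits <- function(parameter) {
  ifelse(parameter == "auc_ratio", 1L, 0L)
}

#' Round a summary table to reporting precision
#'
#' Concentrations, half-lives and AUCs are reported to the integer,
#' the AUC ratio to one decimal; full precision should be retained for any
#' further computation, so this is a presentation-only step.
#'
#' @param summary_table Output of [build_summary_table()].
#' @return The same tibble with numeric cells rounded.
#' @export
format_summary_table <- function(summary_table) {
  num_cols <- c("geometric_mean", "ci_lower", "ci_upper", "median",
                "min", "max", "q1", "q3")
  dplyr::mutate(
    summary_table,
    dplyr::across(dplyr::all_of(num_cols),
                  ~ round(.x, report_digits(.data$parameter)))
  )
}
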